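#' Build a transcript exon-phase model from coding lengths
#'
#' A transcript model is an ordered table of exons carrying, for each exon,
#' its coding length (nucleotides of CDS within the exon), its 1-based
#' inclusive CDS coordinates (HGVS c. convention, c.1 = A of the start codon),
#' and the phase of the flanking introns. The phase at an exon boundary is the
#' cumulative coding length mod 3 at that boundary: phase 0 means the boundary
#' falls between codons. An exon is *symmetric* when its flanking introns share
#' a phase, which holds exactly when its coding length is divisible by 3;
#' removing a symmetric exon (or any run of exons with total length divisible
#' by 3) preserves the downstream reading frame.
#'
#' @param coding_length integer vector of per-exon coding lengths, in exon
#'   order. All values must be >= 1.
#' @param exon integer exon numbers; defaults to `1:length(coding_length)` and
#'   must be exactly that sequence (models are always complete, ordered
#'   transcripts).
#' @return A `transcript_model`: a data frame with columns `exon`, `c_start`,
#'   `c_end`, `coding_length`, `start_phase`, `end_phase`, `symmetric`, and an
#'   attribute `cds_length` (total coding nucleotides).
#' @examples
#' t <- transcript_model(c(10, 21, 14))
#' t$symmetric     # FALSE TRUE FALSE
#' attr(t, "cds_length")
#' @seealso [dmd_transcript()] for the bundled 79-exon dystrophin model,
#'   [load_transcript()] to read a model from a coordinate table.
#' @export
transcript_model <- function(coding_length, exon = seq_along(coding_length)) {
  coding_length <- as.integer(coding_length)
  exon <- as.integer(exon)
  if (length(coding_length) == 0L)
    stop("transcript must have at least one exon")
  if (anyNA(coding_length) || any(coding_length < 1L))
    stop("coding lengths must be positive integers")
  if (!identical(exon, seq_along(coding_length)))
    stop("exon numbers must be exactly 1..", length(coding_length),
         " in order")
  c_end <- cumsum(coding_length)
  c_start <- c(1L, c_end[-length(c_end)] + 1L)
  df <- data.frame(
    exon = exon,
    c_start = c_start,
    c_end = c_end,
    coding_length = coding_length,
    start_phase = (c_start - 1L) %% 3L,
    end_phase = c_end %% 3L,
    symmetric = coding_length %% 3L == 0L
  )
  structure(df,
            cds_length = c_end[length(c_end)],
            class = c("transcript_model", "data.frame"))
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("Transcript model: %d exons, CDS %d nt (%d symmetric exons)\n",
              nrow(x), attr(x, "cds_length"), sum(x$symmetric)))
  NextMethod()
  invisible(x)
}

#' Load a transcript model from an exon coordinate table
#'
#' Reads a tab-separated table with header `exon  c_start  c_end` (1-based
#' inclusive CDS coordinates) and returns a validated [transcript_model()].
#' Phases and symmetry flags are always recomputed from the coordinates,
#' never trusted from the file.
#'
#' @param path path to the TSV file.
#' @param n_exons required exon count, or `NULL` to accept any. Defaults to
#'   79, the dystrophin Dp427m exon count.
#' @return A `transcript_model`.
#' @export
load_transcript <- function(path, n_exons = 79L) {
  if (!file.exists(path)) stop("transcript fixture not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("exon", "c_start", "c_end")
  if (!all(need %in% names(df)))
    stop("fixture must have columns: ", paste(need, collapse = ", "))
  if (anyNA(df$exon) || anyNA(df$c_start) || anyNA(df$c_end))
    stop("fixture contains missing values")
  if (anyDuplicated(df$exon))
    stop("duplicate exon index: ",
         paste(unique(df$exon[duplicated(df$exon)]), collapse = ", "))
  df <- df[order(df$exon), , drop = FALSE]
  if (!is.null(n_exons) && nrow(df) != n_exons)
    stop("expected ", n_exons, " exons, found ", nrow(df))
  if (!identical(as.integer(df$exon), seq_len(nrow(df))))
    stop("exon numbers must be exactly 1..", nrow(df))
  if (df$c_start[1] != 1L)
    stop("exon 1 must start at c.1 (CDS coordinates)")
  bad <- which(df$c_end < df$c_start)
  if (length(bad)) stop("exon ", df$exon[bad[1]], ": c_end precedes c_start")
  if (nrow(df) > 1L) {
    gap <- which(df$c_start[-1] != df$c_end[-nrow(df)] + 1L)
    if (length(gap))
      stop("non-contiguous c. coordinates between exon ", df$exon[gap[1]],
           " and exon ", df$exon[gap[1] + 1L])
  }
  transcript_model(df$c_end - df$c_start + 1L)
}

#' The bundled dystrophin (Dp427m) transcript model
#'
#' Loads the 79-exon coding-sequence exon table shipped with the package and
#' verifies it with [validate_fixture()] before returning it. The table is a
#' curated reconstruction of the muscle full-length dystrophin transcript
#' (RefSeq NM_004006) CDS exon structure: 11058 coding nucleotides (3685
#' residues plus stop), with exon 52 spanning c.7543-c.7660 and the
#' exon 3-9 and exon 45-55 segments each a multiple of 3 nucleotides.
#'
#' @return A validated 79-exon `transcript_model`.
#' @export
dmd_transcript <- function() {
  path <- system.file("extdata", "dmd_dp427m_exons.tsv", package = "dmdskip",
                      mustWork = TRUE)
  t <- load_transcript(path, n_exons = 79L)
  rep <- validate_fixture(t)
  if (!all(rep$passed))
    stop("bundled dystrophin fixture failed validation: ",
         paste(rep$check[!rep$passed], collapse = "; "))
  t
}

#' Total coding length of a run of exons
#'
#' @param t a `transcript_model`.
#' @param first,last exon indices, `1 <= first <= last <= nrow(t)`.
#' @return Integer: sum of coding lengths of exons `first..last`.
#' @examples
#' t <- dmd_transcript()
#' segment_length(t, 52, 52)  # 118
#' segment_length(t, 45, 55) %% 3  # 0: the 45-55 cocktail region is in-frame
#' @export
segment_length <- function(t, first, last) {
  check_exon_range(t, first, last)
  sum(t$coding_length[first:last])
}

#' Is an exon symmetric (frame-preserving on removal)?
#'
#' @inheritParams segment_length
#' @param e exon index.
#' @return `TRUE` iff the exon's coding length is divisible by 3, i.e. its
#'   flanking introns share a phase.
#' @export
is_symmetric <- function(t, e) {
  check_exon_range(t, e, e)
  t$coding_length[e] %% 3L == 0L
}

check_exon_range <- function(t, first, last) {
  stopifnot(inherits(t, "transcript_model"))
  n <- nrow(t)
  if (length(first) != 1L || length(last) != 1L ||
      is.na(first) || is.na(last) ||
      first < 1L || last > n || first > last)
    stop("exon indices out of range: need 1 <= first <= last <= ", n,
         ", got [", first, ", ", last, "]")
  invisible(TRUE)
}

#' Validate the dystrophin fixture against its anchor facts
#'
#' Runs the checks that pin the bundled exon table to independently known
#' facts about the Dp427m coding sequence: 79 exons; exon 52 spanning
#' c.7543-c.7660 (so 118 nt); the multi-exon cocktail regions 45-55 and 3-9
#' in-frame (both are observed as whole-region deletions in mild/asymptomatic
#' patients); contiguous c. coordinates; and total CDS length 11058 nt.
#'
#' @param t a `transcript_model`.
#' @return A data frame of class `fixture_report` with columns `check`,
#'   `passed`, `detail`. All checks passing is a precondition for using a
#'   fixture with the downstream cohort analysis.
#' @export
validate_fixture <- function(t) {
  stopifnot(inherits(t, "transcript_model"))
  checks <- list()
  add <- function(check, passed, detail)
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, passed = passed, detail = detail)

  add("exon count 79", nrow(t) == 79L, sprintf("found %d", nrow(t)))
  contig <- t$c_start[1] == 1L &&
    (nrow(t) == 1L || all(t$c_start[-1] == t$c_end[-nrow(t)] + 1L))
  add("contiguous c. coordinates", contig, "")
  if (nrow(t) >= 52L) {
    add("exon 52 anchor c.7543-7660",
        t$c_start[52] == 7543L && t$c_end[52] == 7660L,
        sprintf("found c.%d-%d", t$c_start[52], t$c_end[52]))
  } else {
    add("exon 52 anchor c.7543-7660", FALSE, "exon 52 absent")
  }
  if (nrow(t) >= 55L) {
    s <- segment_length(t, 45L, 55L)
    add("exons 45-55 in-frame", s %% 3L == 0L, sprintf("length %d", s))
  } else add("exons 45-55 in-frame", FALSE, "exons absent")
  if (nrow(t) >= 9L) {
    s <- segment_length(t, 3L, 9L)
    add("exons 3-9 in-frame", s %% 3L == 0L, sprintf("length %d", s))
  } else add("exons 3-9 in-frame", FALSE, "exons absent")
  add("CDS length 11058", attr(t, "cds_length") == 11058L,
      sprintf("found %d", attr(t, "cds_length")))

  out <- do.call(rbind, checks)
  class(out) <- c("fixture_report", "data.frame")
  out
}

#' @export
print.fixture_report <- function(x, ...) {
  status <- ifelse(x$passed, "PASS", "FAIL")
  for (i in seq_len(nrow(x)))
    cat(sprintf("[%s] %s%s\n", status[i], x$check[i],
                ifelse(nzchar(x$detail[i]), paste0(" (", x$detail[i], ")"),
                       "")))
  invisible(x)
}
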