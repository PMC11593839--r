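#' Parse a simplified HGVS c.-notation variant into a mutation record
#'
#' Supports the coding-DNA subset needed for exon-level dystrophin analysis:
#'
#' * `c.<pos>_<pos>del` / `c.<pos>_<pos>dup` whose endpoints coincide exactly
#'   with exon boundaries and span one or more full exons become exon-range
#'   deletions/duplications (e.g. `c.7543_7660del` is the deletion of
#'   exon 52);
#' * single-position or intra-exonic small variants (`c.<pos><ref>><alt>`,
#'   `c.<pos>del`, `c.<pos>_<pos>ins...`, `delins`, small `dup`) become
#'   `small_lesion(intra)` in the containing exon;
#' * positions with an intronic offset `+n` become `small_lesion(donor)` on
#'   the exon whose last coding base anchors the offset (e.g. `c.7660+1G>A`
#'   is a donor-site lesion of exon 52); offsets `-n` become
#'   `small_lesion(acceptor)` on the exon whose first coding base anchors the
#'   offset (e.g. `c.7543-2A>G`, acceptor of exon 52).
#'
#' A del/dup range that is not exon-boundary-aligned yet spans more than one
#' exon is *unsupported* and raises an error (such records need manual
#' exon-level encoding); the parser never silently reinterprets its input.
#'
#' @param s an HGVS c. string. ASCII hyphen, Unicode minus, and en dash are
#'   accepted as the offset sign.
#' @param t a `transcript_model` giving the c. exon boundaries.
#' @param id record identifier for the resulting mutation (default `s`).
#' @return A one-row mutation data frame (see [mutation()]).
#' @export
parse_hgvs_lite <- function(s, t, id = s) {
  stopifnot(inherits(t, "transcript_model"))
  s0 <- s
  s <- gsub("−", "-", gsub("–", "-", trimws(s)))
  if (!startsWith(s, "c."))
    stop("unsupported HGVS string (expected c. prefix): ", s0)
  body <- substring(s, 3L)

  pos_re <- "(\\d+)([+-]\\d+)?"
  m_range <- regmatches(body, regexec(
    paste0("^", pos_re, "_", pos_re, "(del|dup|ins|delins)[A-Za-z>]*$"),
    body))[[1]]
  m_single <- regmatches(body, regexec(
    paste0("^", pos_re, "(del|dup|ins|delins|[A-Za-z]+>[A-Za-z]+)",
           "[A-Za-z]*$"),
    body))[[1]]

  if (length(m_range)) {
    p1 <- as.integer(m_range[2]); o1 <- offset_val(m_range[3])
    p2 <- as.integer(m_range[4]); o2 <- offset_val(m_range[5])
    kind <- m_range[6]
    if (o1 != 0L || o2 != 0L)
      stop("unsupported: intronic offsets on a range: ", s0)
    check_cds_pos(p1, t, s0); check_cds_pos(p2, t, s0)
    if (p1 > p2) stop("range start after end: ", s0)
    e1 <- exon_of(p1, t); e2 <- exon_of(p2, t)
    aligned <- p1 == t$c_start[e1] && p2 == t$c_end[e2]
    if (kind %in% c("del", "dup") && aligned) {
      return(mutation(id, ifelse(kind == "del", "deletion", "duplication"),
                      first_exon = e1, last_exon = e2, raw = s0, t = t))
    }
    if (e1 != e2)
      stop("unsupported: range not exon-boundary-aligned and spanning ",
           "more than one exon (needs manual exon-level encoding): ", s0)
    return(mutation(id, "small_lesion", lesion_exon = e1,
                    lesion_site = "intra", raw = s0, t = t))
  }

  if (length(m_single)) {
    p <- as.integer(m_single[2]); o <- offset_val(m_single[3])
    check_cds_pos(p, t, s0)
    if (o > 0L) {
      e <- which(t$c_end == p)
      if (!length(e))
        stop("donor offset must anchor at an exon's last coding base: ", s0)
      return(mutation(id, "small_lesion", lesion_exon = e,
                      lesion_site = "donor", raw = s0, t = t))
    }
    if (o < 0L) {
      e <- which(t$c_start == p)
      if (!length(e))
        stop("acceptor offset must anchor at an exon's first coding base: ",
             s0)
      return(mutation(id, "small_lesion", lesion_exon = e,
                      lesion_site = "acceptor", raw = s0, t = t))
    }
    return(mutation(id, "small_lesion", lesion_exon = exon_of(p, t),
                    lesion_site = "intra", raw = s0, t = t))
  }

  stop("unsupported HGVS string: ", s0)
}

offset_val <- function(x) {
  if (is.na(x) || !nzchar(x)) 0L else as.integer(x)
}

check_cds_pos <- function(p, t, s) {
  if (p < 1L || p > attr(t, "cds_length"))
    stop("position c.", p, " outside CDS (1..", attr(t, "cds_length"),
         "): ", s)
  invisible(TRUE)
}

exon_of <- function(p, t) {
  which(t$c_start <= p & p <= t$c_end)[1]
}

#' Write an exon-range mutation as boundary-aligned HGVS c. notation
#'
#' Inverse of [parse_hgvs_lite()] for machine-generated deletion/duplication
#' records; small lesions have no canonical nucleotide-level form and return
#' their `raw` string (or `NA`).
#'
#' @param m a one-row mutation data frame.
#' @param t a `transcript_model`.
#' @return An HGVS c. string, or `NA` for small lesions without `raw`.
#' @export
to_hgvs <- function(m, t) {
  stopifnot(nrow(m) == 1L)
  if (m$mclass == "small_lesion") return(m$raw)
  sprintf("c.%d_%d%s", t$c_start[m$first_exon], t$c_end[m$last_exon],
          ifelse(m$mclass == "deletion", "del", "dup"))
}
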