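#' Configuration for skip-strategy enumeration
#'
#' @param multi_ranges list of length-2 integer vectors giving the multi-exon
#'   cocktail ranges to evaluate. Each range must be in-frame on the
#'   transcript it is used with. Defaults to the two dystrophin hotspot
#'   cocktails, exons 3-9 and exons 45-55.
#' @param splice_loss_convention which exon a splice-site lesion removes from
#'   the transcript. `"own_exon"` (default): a mutated donor or acceptor
#'   abolishes recognition of its own exon, which is lost — standard splicing
#'   biology. `"paper_literal"`: a donor lesion removes the downstream
#'   neighbour (`e + 1`) and an acceptor lesion the upstream neighbour
#'   (`e - 1`).
#' @return A list of class `skip_config`.
#' @export
skip_config <- function(multi_ranges = list(c(3L, 9L), c(45L, 55L)),
                        splice_loss_convention = c("own_exon",
                                                   "paper_literal")) {
  splice_loss_convention <- match.arg(splice_loss_convention)
  stopifnot(is.list(multi_ranges))
  for (r in multi_ranges)
    if (length(r) != 2L || r[1] > r[2])
      stop("each multi range must be c(first, last) with first <= last")
  structure(list(multi_ranges = lapply(multi_ranges, as.integer),
                 splice_loss_convention = splice_loss_convention),
            class = "skip_config")
}

# skippable exons exclude the first (start codon) and last (stop codon) exon
skippable_range <- function(t) c(2L, nrow(t) - 1L)

new_strategies <- function(targets = list(), category = character(),
                           excluded = list(), note = character(),
                           label = NULL) {
  if (is.null(label))
    label <- vapply(seq_along(category), function(i)
      strategy_label(targets[[i]], category[i]), character(1))
  df <- data.frame(label = label, category = category, note = note,
                   stringsAsFactors = FALSE)
  df$targets <- lapply(targets, function(x) sort(as.integer(x)))
  df$excluded <- lapply(excluded, function(x) sort(as.integer(x)))
  class(df) <- c("skip_strategies", "data.frame")
  df
}

empty_strategies <- function() {
  new_strategies(list(), character(), list(), character(),
                 label = character())
}

one_strategy <- function(targets, category, excluded, note = "",
                         label = NULL) {
  new_strategies(list(targets), category, list(excluded), note, label = label)
}

bind_strategies <- function(...) {
  dfs <- Filter(function(x) !is.null(x) && nrow(x) > 0, list(...))
  if (!length(dfs)) return(empty_strategies())
  out <- do.call(rbind, dfs)
  class(out) <- c("skip_strategies", "data.frame")
  out
}

#' Canonical strategy label
#'
#' Single targets print as `"51"`, double targets as `"51 & 52"` (ascending),
#' multi-exon cocktails as `"45-55"`, and the no-target case (a splice lesion
#' whose induced exon loss is already in-frame) as `"(none)"`.
#'
#' @param targets integer vector of skipped exons.
#' @param category `"single"`, `"double"`, `"multi"`, or `"none"`.
#' @return A character label.
#' @export
strategy_label <- function(targets, category) {
  targets <- sort(as.integer(targets))
  switch(category,
         single = as.character(targets),
         double = paste(targets, collapse = " & "),
         multi = paste0(targets[1], "-", targets[length(targets)]),
         none = "(none)",
         stop("unknown strategy category: ", category))
}

#' Reading-frame status of an exon-range deletion
#'
#' Under the reading-frame rule, a deletion disrupts the frame iff the total
#' coding length of the deleted exons is not a multiple of 3.
#'
#' @param t a `transcript_model`.
#' @param first,last deleted exon range.
#' @return `"frameshift"` or `"in_frame"`.
#' @export
deletion_frame_status <- function(t, first, last) {
  if (segment_length(t, first, last) %% 3L == 0L) "in_frame" else "frameshift"
}

#' Enumerate frame-restoring skips for a frameshift deletion
#'
#' Considers the exons immediately flanking the deletion: target sets drawn
#' from \{first-2, first-1, last+1, last+2\} of size 1 or 2 such that the
#' excluded region (deleted exons plus skipped exons) is a contiguous exon
#' run inside the skippable range whose total coding length is a multiple
#' of 3. The admissible shapes are `{first-1}`, `{last+1}`,
#' `{first-2, first-1}`, `{last+1, last+2}`, and `{first-1, last+1}`.
#'
#' @inheritParams deletion_frame_status
#' @return A strategy table (zero rows when nothing restores the frame).
#' @examples
#' t <- dmd_transcript()
#' deletion_skips(t, 52, 52)$label   # "51" "53"
#' deletion_skips(t, 46, 50)$label   # "45 & 51"
#' @export
deletion_skips <- function(t, first, last) {
  check_exon_range(t, first, last)
  if (deletion_frame_status(t, first, last) != "frameshift")
    stop("deletion_skips called on an in-frame deletion (exons ",
         first, "-", last, ")")
  shapes <- list(first - 1L, last + 1L,
                 c(first - 2L, first - 1L), c(last + 1L, last + 2L),
                 c(first - 1L, last + 1L))
  sk <- skippable_range(t)
  out <- empty_strategies()
  for (T in shapes) {
    if (any(T < sk[1] | T > sk[2])) next
    excl <- sort(unique(c(first:last, T)))
    if (any(diff(excl) != 1L)) next            # excluded run must be contiguous
    if (sum(t$coding_length[excl]) %% 3L != 0L) next
    out <- bind_strategies(out, one_strategy(
      T, ifelse(length(T) == 1L, "single", "double"), excl))
  }
  out
}

# which exon a splice-site lesion removes from the transcript
splice_lost_exon <- function(m, t, config) {
  e <- m$lesion_exon
  l <- switch(config$splice_loss_convention,
              own_exon = e,
              paper_literal = if (m$lesion_site == "donor") e + 1L else e - 1L)
  if (l < 1L || l > nrow(t)) NA_integer_ else l
}

#' Enumerate frame-restoring skips for a small lesion
#'
#' Intra-exonic lesions in a symmetric exon are removed by skipping that exon
#' alone; in an asymmetric exon, the lesion-bearing exon must be skipped
#' together with an adjacent exon such that the pair's combined coding length
#' is a multiple of 3. Splice-site lesions first resolve the exon lost from
#' the transcript (see [skip_config()]); if that exon is symmetric the induced
#' loss is already in-frame and no ASO is needed, otherwise the induced
#' single-exon deletion is rescued exactly as a deletion would be.
#'
#' The lesion's own length change (point mutation or small indel) is ignored:
#' once the lesion-bearing exon is excluded, only the excluded exons' coding
#' lengths matter.
#'
#' @param t a `transcript_model`.
#' @param m a one-row small-lesion mutation.
#' @param config a [skip_config()].
#' @return A strategy table; empty when no admissible targets exist (for
#'   example a lesion in the first or last exon).
#' @export
small_lesion_skips <- function(t, m, config = skip_config()) {
  stopifnot(nrow(m) == 1L, m$mclass == "small_lesion")
  check_exon_range(t, m$lesion_exon, m$lesion_exon)
  sk <- skippable_range(t)
  e <- m$lesion_exon
  if (m$lesion_site == "intra") {
    if (is_symmetric(t, e)) {
      if (e < sk[1] || e > sk[2]) return(empty_strategies())
      return(one_strategy(e, "single", e))
    }
    out <- empty_strategies()
    for (p in list(c(e - 1L, e), c(e, e + 1L))) {
      if (any(p < sk[1] | p > sk[2])) next
      if (sum(t$coding_length[p]) %% 3L != 0L) next
      out <- bind_strategies(out, one_strategy(p, "double", p))
    }
    return(out)
  }
  # splice-site lesion: resolve the lost exon
  l <- splice_lost_exon(m, t, config)
  if (is.na(l)) return(empty_strategies())
  if (is_symmetric(t, l))
    return(one_strategy(integer(0), "none", l, note = "no-ASO-needed"))
  deletion_skips(t, l, l)
}

#' Enumerate frame-restoring skips for a frameshift duplication
#'
#' Under the one-copy-skip model, skipping one copy of a subset `S` of the
#' duplicated exons leaves one extra in-frame copy iff the duplication's
#' total coding length minus `S`'s is a multiple of 3. `S` may be a single
#' exon or two adjacent exons. For a single-exon duplication the unique
#' candidate is the duplicated exon itself, which always qualifies (removing
#' one copy restores the wild type). ASOs cannot distinguish the copies; if
#' the original is mistargeted the frame is disrupted, which is surfaced as a
#' note rather than a disqualifier.
#'
#' @inheritParams deletion_frame_status
#' @return A strategy table.
#' @export
duplication_skips <- function(t, first, last) {
  check_exon_range(t, first, last)
  seg <- segment_length(t, first, last)
  if (seg %% 3L == 0L)
    stop("duplication_skips called on an in-frame duplication (exons ",
         first, "-", last, ")")
  sk <- skippable_range(t)
  out <- empty_strategies()
  for (e in first:last)
    if (e >= sk[1] && e <= sk[2] && (seg - t$coding_length[e]) %% 3L == 0L)
      out <- bind_strategies(out, one_strategy(
        e, "single", integer(0), note = "one-copy-skip"))
  if (last > first)
    for (e in first:(last - 1L)) {
      p <- c(e, e + 1L)
      if (any(p < sk[1] | p > sk[2])) next
      if ((seg - sum(t$coding_length[p])) %% 3L == 0L)
        out <- bind_strategies(out, one_strategy(
          p, "double", integer(0), note = "one-copy-skip"))
    }
  out
}

#' Adjacent-exon rescue after skipping both copies of a duplicated exon
#'
#' ASOs targeting a single-exon duplication sometimes exclude both copies,
#' turning the duplication into a frameshift single-exon deletion. When an
#' adjacent exon `f` satisfies `coding_length(e) + coding_length(f) == 0
#' (mod 3)`, additionally skipping `f` leaves an in-frame transcript (wild
#' type minus `e` minus `f`).
#'
#' @param t a `transcript_model`.
#' @param e the duplicated exon (must be frameshift, i.e. asymmetric).
#' @return A strategy table of qualifying neighbours, noted
#'   `"rescue-after-double-copy-skip"`; empty when no neighbour qualifies.
#' @export
duplication_double_copy_rescue <- function(t, e) {
  check_exon_range(t, e, e)
  if (is_symmetric(t, e))
    stop("double-copy rescue is defined for frameshift (asymmetric) ",
         "single-exon duplications; exon ", e, " is symmetric")
  sk <- skippable_range(t)
  out <- empty_strategies()
  for (f in c(e - 1L, e + 1L)) {
    if (f < sk[1] || f > sk[2]) next
    if ((t$coding_length[e] + t$coding_length[f]) %% 3L != 0L) next
    out <- bind_strategies(out, one_strategy(
      f, "single", c(e, f), note = "rescue-after-double-copy-skip"))
  }
  out
}

#' Is a multi-exon cocktail applicable to a mutation?
#'
#' A cocktail skipping the whole (in-frame) range `range_first..range_last`
#' applies to a frameshift deletion iff the deletion lies entirely inside the
#' range (the skip then produces the full in-frame range deletion); to a
#' small lesion iff the lesion-bearing (or splice-induced lost) exon lies in
#' the range; and never to duplications.
#'
#' @param t a `transcript_model`.
#' @param m a one-row mutation.
#' @param range_first,range_last the cocktail range (must be in-frame on `t`).
#' @param config a [skip_config()] (splice-loss convention).
#' @return Logical.
#' @export
multi_skip_applicable <- function(t, m, range_first, range_last,
                                  config = skip_config()) {
  check_exon_range(t, range_first, range_last)
  if (segment_length(t, range_first, range_last) %% 3L != 0L)
    stop("cocktail range ", range_first, "-", range_last,
         " is not in-frame on this transcript")
  stopifnot(nrow(m) == 1L)
  switch(m$mclass,
    deletion = {
      deletion_frame_status(t, m$first_exon, m$last_exon) == "frameshift" &&
        m$first_exon >= range_first && m$last_exon <= range_last
    },
    small_lesion = {
      e <- if (m$lesion_site == "intra") m$lesion_exon
           else splice_lost_exon(m, t, config)
      !is.na(e) && e >= range_first && e <= range_last
    },
    duplication = FALSE)
}

#' Annotate one mutation with its frame status and all skip strategies
#'
#' Dispatches to the class-specific enumerators, evaluates every configured
#' multi-exon cocktail, and de-duplicates strategies by target set and
#' category. In-frame deletions and duplications receive no strategies: an
#' in-frame deletion has no frame disruption for exon-skipping to restore.
#' Small lesions have frame status `"not_applicable"` (the mod-3 arithmetic
#' does not classify sub-exonic lesions).
#'
#' Every returned deletion/small-lesion strategy is checked for soundness:
#' the excluded region's total coding length must be a multiple of 3.
#'
#' @param t a `transcript_model`.
#' @param m a one-row mutation.
#' @param config a [skip_config()].
#' @return An `annotation`: list with `mutation_id`, `frame_status`, and
#'   `strategies` (a strategy table).
#' @examples
#' t <- dmd_transcript()
#' a <- annotate(t, parse_hgvs_lite("c.7543_7660del", t))
#' a$strategies$label   # "51" "53" "45-55"
#' @export
annotate <- function(t, m, config = skip_config()) {
  stopifnot(nrow(m) == 1L)
  validate_mutations(m, t)
  strategies <- empty_strategies()
  frame_status <- switch(m$mclass,
    deletion = deletion_frame_status(t, m$first_exon, m$last_exon),
    duplication = deletion_frame_status(t, m$first_exon, m$last_exon),
    small_lesion = "not_applicable")

  if (m$mclass == "deletion" && frame_status == "frameshift") {
    strategies <- deletion_skips(t, m$first_exon, m$last_exon)
  } else if (m$mclass == "small_lesion") {
    strategies <- small_lesion_skips(t, m, config)
  } else if (m$mclass == "duplication" && frame_status == "frameshift") {
    strategies <- duplication_skips(t, m$first_exon, m$last_exon)
    if (m$first_exon == m$last_exon)
      strategies <- bind_strategies(
        strategies, duplication_double_copy_rescue(t, m$first_exon))
  }

  for (r in config$multi_ranges) {
    if (r[2] > nrow(t)) next
    if (multi_skip_applicable(t, m, r[1], r[2], config)) {
      already_out <- if (m$mclass == "deletion") m$first_exon:m$last_exon
                     else integer(0)
      strategies <- bind_strategies(strategies, one_strategy(
        setdiff(r[1]:r[2], already_out), "multi", r[1]:r[2],
        label = paste0(r[1], "-", r[2])))
    }
  }

  # de-duplicate by (targets, category)
  if (nrow(strategies)) {
    key <- paste(vapply(strategies$targets, paste, character(1),
                        collapse = ","), strategies$category)
    strategies <- strategies[!duplicated(key), , drop = FALSE]
  }

  # soundness: excluded region of deletion/small-lesion strategies is in-frame
  if (m$mclass %in% c("deletion", "small_lesion")) {
    for (i in seq_len(nrow(strategies))) {
      ex <- strategies$excluded[[i]]
      if (length(ex) && sum(t$coding_length[ex]) %% 3L != 0L)
        stop("internal error: strategy ", strategies$label[i],
             " excludes an out-of-frame region")
    }
  }

  structure(list(mutation_id = m$id, frame_status = frame_status,
                 strategies = strategies),
            class = "annotation")
}

#' @export
print.annotation <- function(x, ...) {
  cat(sprintf("Mutation %s: %s\n", x$mutation_id, x$frame_status))
  if (nrow(x$strategies) == 0L) {
    cat("  no applicable exon-skipping strategy\n")
  } else {
    for (i in seq_len(nrow(x$strategies)))
      cat(sprintf("  skip %-9s [%s]%s\n", x$strategies$label[i],
                  x$strategies$category[i],
                  ifelse(nzchar(x$strategies$note[i]),
                         paste0(" ", x$strategies$note[i]), "")))
  }
  invisible(x)
}

#' Annotate every mutation in a cohort
#'
#' @param t a `transcript_model`.
#' @param ms mutation data frame.
#' @param config a [skip_config()].
#' @return A list of [annotate()] results, named by mutation id.
#' @export
annotate_cohort <- function(t, ms, config = skip_config()) {
  validate_mutations(ms, t)
  anns <- lapply(seq_len(nrow(ms)), function(i) annotate(t, ms[i, ], config))
  names(anns) <- ms$id
  anns
}

#' Flatten annotations into a long strategy table
#'
#' @param annotations a list of [annotate()] results.
#' @return Data frame with one row per (mutation, strategy): columns `id`,
#'   `frame_status`, `label`, `category`, `note`.
#' @export
strategy_table <- function(annotations) {
  rows <- lapply(annotations, function(a) {
    if (nrow(a$strategies) == 0L)
      return(data.frame(id = a$mutation_id, frame_status = a$frame_status,
                        label = NA_character_, category = NA_character_,
                        note = NA_character_, stringsAsFactors = FALSE))
    data.frame(id = a$mutation_id, frame_status = a$frame_status,
               label = a$strategies$label, category = a$strategies$category,
               note = a$strategies$note, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export annotations as JSON
#'
#' One object per mutation: `id`, `frame_status`, and `strategies` with
#' `targets`, `category`, `note`.
#'
#' @param annotations a list of [annotate()] results.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  objs <- lapply(annotations, function(a) list(
    id = a$mutation_id,
    frame_status = a$frame_status,
    strategies = lapply(seq_len(nrow(a$strategies)), function(i) list(
      targets = a$strategies$targets[[i]],
      category = a$strategies$category[i],
      label = a$strategies$label[i],
      note = a$strategies$note[i]))))
  jsonlite::write_json(unname(objs), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
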