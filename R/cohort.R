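#' Cohort-level applicability summary
#'
#' Aggregates per-mutation annotations into per-strategy applicability counts
#' and percentages by mutation class, plus a per-class summary of single,
#' double, single-or-double, and multi-exon skipping applicability. A
#' mutation contributes at most once per strategy but may contribute to many
#' strategies. Splice lesions whose induced exon loss is already in-frame
#' ("no ASO needed") carry an empty target set and are excluded from
#' per-strategy rows and from the single/double columns.
#'
#' @param annotations list of [annotate()] results, aligned with `mutations`
#'   by id.
#' @param mutations the mutation data frame the annotations were computed
#'   from (already phenotype-filtered).
#' @param denominator `"all"`: per-class percentages use all records of the
#'   class (deletions including in-frame ones) and overall percentages the
#'   full cohort. `"frameshift"`: deletions use frameshift-only denominators;
#'   the overall denominator is the sum of the class denominators.
#' @return A `cohort_summary`: list with `denominators` (named counts),
#'   `strategy_rows` (label, category, per-class and overall counts and
#'   percentages, sorted by overall percentage descending, ties by label),
#'   and `class_rows` (per class and overall: percent amenable by single /
#'   double-only / single-or-double / multi skipping; the multi column is not
#'   computed for duplications).
#' @export
summarize_cohort <- function(annotations, mutations,
                             denominator = c("all", "frameshift")) {
  denominator <- match.arg(denominator)
  if (nrow(mutations) == 0L)
    stop("empty cohort: denominators are undefined")
  if (anyDuplicated(mutations$id))
    stop("duplicate mutation ids")
  if (!setequal(names(annotations), mutations$id) ||
      length(annotations) != nrow(mutations))
    stop("annotations and mutations are not aligned by id")
  annotations <- annotations[mutations$id]

  classes <- c("deletion", "small_lesion", "duplication")
  n_class <- vapply(classes, function(cl) sum(mutations$mclass == cl),
                    integer(1))
  if (denominator == "frameshift") {
    fs <- vapply(annotations, function(a) a$frame_status, character(1))
    n_class["deletion"] <- sum(mutations$mclass == "deletion" &
                                 fs[mutations$id] == "frameshift")
    n_total <- sum(n_class)
  } else {
    n_total <- nrow(mutations)
  }

  long <- strategy_table(annotations)
  long <- long[!is.na(long$label) & long$category != "none", , drop = FALSE]
  long$mclass <- mutations$mclass[match(long$id, mutations$id)]
  long <- long[!duplicated(long[, c("id", "label", "category")]), ,
               drop = FALSE]

  if (nrow(long)) {
    labs <- unique(long[, c("label", "category")])
    counts <- lapply(classes, function(cl) {
      sub <- long[long$mclass == cl, , drop = FALSE]
      vapply(seq_len(nrow(labs)), function(i)
        sum(sub$label == labs$label[i] & sub$category == labs$category[i]),
        integer(1))
    })
    names(counts) <- classes
    strategy_rows <- data.frame(
      label = labs$label, category = labs$category,
      count_deletion = counts$deletion,
      count_small_lesion = counts$small_lesion,
      count_duplication = counts$duplication,
      stringsAsFactors = FALSE)
    strategy_rows$count_total <- strategy_rows$count_deletion +
      strategy_rows$count_small_lesion + strategy_rows$count_duplication
    pct <- function(count, denom)
      if (denom > 0) 100 * count / denom else rep(NA_real_, length(count))
    strategy_rows$pct_deletion <- pct(strategy_rows$count_deletion,
                                      n_class["deletion"])
    strategy_rows$pct_small_lesion <- pct(strategy_rows$count_small_lesion,
                                          n_class["small_lesion"])
    strategy_rows$pct_duplication <- pct(strategy_rows$count_duplication,
                                         n_class["duplication"])
    strategy_rows$pct_total <- pct(strategy_rows$count_total, n_total)
    ord <- order(-strategy_rows$pct_total, strategy_rows$label)
    strategy_rows <- strategy_rows[ord, , drop = FALSE]
    rownames(strategy_rows) <- NULL
  } else {
    strategy_rows <- data.frame(
      label = character(), category = character(),
      count_deletion = integer(), count_small_lesion = integer(),
      count_duplication = integer(), count_total = integer(),
      pct_deletion = numeric(), pct_small_lesion = numeric(),
      pct_duplication = numeric(), pct_total = numeric(),
      stringsAsFactors = FALSE)
  }

  # per-mutation amenability flags
  has_cat <- function(a, cat) any(a$strategies$category == cat)
  flags <- data.frame(
    id = mutations$id, mclass = mutations$mclass,
    single = vapply(annotations, has_cat, logical(1), cat = "single"),
    double = vapply(annotations, has_cat, logical(1), cat = "double"),
    multi = vapply(annotations, has_cat, logical(1), cat = "multi"),
    stringsAsFactors = FALSE)
  if (denominator == "frameshift") {
    fs <- vapply(annotations, function(a) a$frame_status, character(1))
    keep <- !(flags$mclass == "deletion" & fs[flags$id] != "frameshift")
    flags <- flags[keep, , drop = FALSE]
  }
  class_row <- function(sub, denom, cl) {
    data.frame(
      class = cl, n = denom,
      pct_single = if (denom > 0) 100 * sum(sub$single) / denom else NA,
      pct_double_only = if (denom > 0)
        100 * sum(sub$double & !sub$single) / denom else NA,
      pct_single_or_double = if (denom > 0)
        100 * sum(sub$single | sub$double) / denom else NA,
      pct_multi = if (cl == "duplication") NA else if (denom > 0)
        100 * sum(sub$multi) / denom else NA,
      stringsAsFactors = FALSE)
  }
  class_rows <- do.call(rbind, c(
    lapply(classes, function(cl)
      class_row(flags[flags$mclass == cl, , drop = FALSE],
                n_class[[cl]], cl)),
    list(class_row(flags, n_total, "all"))))
  # the overall multi percentage spans all classes (duplications contribute 0)
  class_rows$pct_multi[class_rows$class == "all"] <-
    if (n_total > 0) 100 * sum(flags$multi) / n_total else NA
  rownames(class_rows) <- NULL

  structure(list(
    denominators = c(n_class, total = n_total),
    denominator_mode = denominator,
    strategy_rows = strategy_rows,
    class_rows = class_rows), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, top = 10L, ...) {
  d <- x$denominators
  cat(sprintf(
    "Cohort summary (%s denominators): %d records (%d del / %d small / %d dup)\n",
    x$denominator_mode, d[["total"]], d[["deletion"]], d[["small_lesion"]],
    d[["duplication"]]))
  cat("\nTop strategies (% of all records):\n")
  sr <- utils::head(x$strategy_rows, top)
  for (i in seq_len(nrow(sr)))
    cat(sprintf("  %2d. %-9s %5.1f%%\n", i, sr$label[i], sr$pct_total[i]))
  cat("\nClass amenability (%):\n")
  print(format(x$class_rows, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Mutation-class composition of a cohort
#'
#' Counts and percentages per mutation class; when a transcript is supplied,
#' deletions (and duplications) are additionally split into frameshift and
#' in-frame records.
#'
#' @param ms mutation data frame (non-empty).
#' @param t optional `transcript_model` for the frame-status split.
#' @return A list with `n`, `class_counts`, `class_pct`, and (with `t`)
#'   `deletion_frame` / `duplication_frame` count-and-percent splits.
#' @examples
#' # the composition arithmetic on published cohort counts:
#' # 1028 deletions + 457 small lesions + 232 duplications
#' @export
composition_report <- function(ms, t = NULL) {
  if (nrow(ms) == 0L) stop("empty mutation list")
  classes <- c("deletion", "small_lesion", "duplication")
  counts <- vapply(classes, function(cl) sum(ms$mclass == cl), integer(1))
  out <- list(n = nrow(ms), class_counts = counts,
              class_pct = 100 * counts / nrow(ms))
  if (!is.null(t)) {
    split_frame <- function(cl) {
      sub <- ms[ms$mclass == cl, , drop = FALSE]
      if (nrow(sub) == 0L)
        return(c(n = 0L, frameshift = 0L, in_frame = 0L,
                 pct_frameshift = NA, pct_in_frame = NA))
      st <- vapply(seq_len(nrow(sub)), function(i)
        deletion_frame_status(t, sub$first_exon[i], sub$last_exon[i]),
        character(1))
      c(n = nrow(sub), frameshift = sum(st == "frameshift"),
        in_frame = sum(st == "in_frame"),
        pct_frameshift = 100 * sum(st == "frameshift") / nrow(sub),
        pct_in_frame = 100 * sum(st == "in_frame") / nrow(sub))
    }
    out$deletion_frame <- split_frame("deletion")
    out$duplication_frame <- split_frame("duplication")
  }
  out
}

#' Write a cohort summary to disk
#'
#' `format = "tsv"` writes the per-strategy table followed by a blank line
#' and the class summary; `format = "json"` writes the whole summary as JSON,
#' which [read_report()] round-trips. Output is deterministic: identical
#' summaries give byte-identical files.
#'
#' @param s a `cohort_summary`.
#' @param path output file.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(s, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(s, "cohort_summary"))
  if (format == "json") {
    jsonlite::write_json(
      list(denominators = as.list(s$denominators),
           denominator_mode = s$denominator_mode,
           strategy_rows = s$strategy_rows,
           class_rows = s$class_rows),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
    return(invisible(path))
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  sr <- s$strategy_rows
  num <- vapply(sr, is.numeric, logical(1)) & !vapply(sr, is.integer,
                                                      logical(1))
  sr[num] <- lapply(sr[num], function(x) formatC(x, digits = 10,
                                                 format = "g"))
  utils::write.table(sr, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines("", con)
  cr <- s$class_rows
  num <- vapply(cr, is.numeric, logical(1)) & !vapply(cr, is.integer,
                                                      logical(1))
  cr[num] <- lapply(cr[num], function(x) formatC(x, digits = 10,
                                                 format = "g"))
  utils::write.table(cr, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a JSON cohort summary written by [write_report()]
#'
#' @param path JSON file path.
#' @return A `cohort_summary`.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    denominators = unlist(x$denominators),
    denominator_mode = x$denominator_mode,
    strategy_rows = as.data.frame(x$strategy_rows),
    class_rows = as.data.frame(x$class_rows)), class = "cohort_summary")
}
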