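MUTATION_CLASSES <- c("deletion", "duplication", "small_lesion")
LESION_SITES <- c("intra", "donor", "acceptor")
PHENOTYPES <- c("DMD", "BMD", "IMD", "DCM", "pending")
MUTATION_COLS <- c("id", "mclass", "first_exon", "last_exon",
                   "lesion_exon", "lesion_site", "phenotype", "raw")

#' Construct a single mutation record
#'
#' A mutation is one of three classes: an exon-range `deletion`, an exon-range
#' `duplication`, or a `small_lesion` (sub-exonic: point mutation, small
#' indel, or splice-site mutation). Deletions and duplications carry
#' `first_exon`/`last_exon`; small lesions carry `lesion_exon` and a
#' `lesion_site` of `"intra"` (within the exon body), `"donor"` (the 5'
#' splice site of the following intron), or `"acceptor"` (the 3' splice site
#' of the preceding intron).
#'
#' @param id opaque record identifier.
#' @param mclass one of `"deletion"`, `"duplication"`, `"small_lesion"`.
#' @param first_exon,last_exon exon range for deletions/duplications
#'   (`first_exon == last_exon` for single-exon events).
#' @param lesion_exon,lesion_site small-lesion fields.
#' @param phenotype one of `"DMD"`, `"BMD"`, `"IMD"`, `"DCM"`, `"pending"`
#'   (case-insensitive).
#' @param raw optional original HGVS string.
#' @param t optional `transcript_model` used to range-check exon indices.
#' @return A one-row mutation data frame.
#' @export
mutation <- function(id, mclass, first_exon = NA, last_exon = NA,
                     lesion_exon = NA, lesion_site = NA,
                     phenotype = "DMD", raw = NA, t = NULL) {
  m <- data.frame(id = as.character(id),
                  mclass = tolower(as.character(mclass)),
                  first_exon = as.integer(first_exon),
                  last_exon = as.integer(last_exon),
                  lesion_exon = as.integer(lesion_exon),
                  lesion_site = ifelse(is.na(lesion_site), NA_character_,
                                       tolower(as.character(lesion_site))),
                  phenotype = normalize_phenotype(phenotype),
                  raw = as.character(raw),
                  stringsAsFactors = FALSE)
  validate_mutations(m, t)
}

normalize_phenotype <- function(x) {
  x <- as.character(x)
  idx <- match(tolower(x), tolower(PHENOTYPES))
  if (anyNA(idx))
    stop("unknown phenotype token: ",
         paste(unique(x[is.na(idx)]), collapse = ", "))
  PHENOTYPES[idx]
}

#' Validate a table of mutation records
#'
#' Checks the class-specific field pattern of every row: deletions and
#' duplications must populate exactly `first_exon <= last_exon` and leave the
#' lesion fields empty; small lesions must populate exactly `lesion_exon` and
#' `lesion_site`. Exon indices are range-checked against `t` when provided.
#'
#' @param ms mutation data frame (see [mutation()]).
#' @param t optional `transcript_model` for exon range checks.
#' @return `ms`, invisibly validated (errors name the offending row/id).
#' @export
validate_mutations <- function(ms, t = NULL) {
  stopifnot(is.data.frame(ms))
  miss <- setdiff(MUTATION_COLS, names(ms))
  if (length(miss))
    stop("mutation table lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(ms$id))
    stop("duplicate mutation id: ",
         paste(unique(ms$id[duplicated(ms$id)]), collapse = ", "))
  n_exons <- if (is.null(t)) 79L else nrow(t)
  for (i in seq_len(nrow(ms))) {
    r <- ms[i, ]
    where <- sprintf("row %d (id %s)", i, r$id)
    if (!r$mclass %in% MUTATION_CLASSES)
      stop(where, ": unknown mutation class '", r$mclass, "'")
    if (!r$phenotype %in% PHENOTYPES)
      stop(where, ": unknown phenotype '", r$phenotype, "'")
    if (r$mclass %in% c("deletion", "duplication")) {
      if (is.na(r$first_exon) || is.na(r$last_exon))
        stop(where, ": ", r$mclass, " needs first_exon and last_exon")
      if (!is.na(r$lesion_exon) || !is.na(r$lesion_site))
        stop(where, ": ", r$mclass, " must not carry lesion fields")
      if (r$first_exon < 1L || r$last_exon > n_exons ||
          r$first_exon > r$last_exon)
        stop(where, ": exon range [", r$first_exon, ", ", r$last_exon,
             "] out of range 1..", n_exons)
    } else {
      if (is.na(r$lesion_exon) || is.na(r$lesion_site))
        stop(where, ": small_lesion needs lesion_exon and lesion_site")
      if (!is.na(r$first_exon) || !is.na(r$last_exon))
        stop(where, ": small_lesion must not carry an exon range")
      if (!r$lesion_site %in% LESION_SITES)
        stop(where, ": unknown lesion_site '", r$lesion_site, "'")
      if (r$lesion_exon < 1L || r$lesion_exon > n_exons)
        stop(where, ": lesion_exon ", r$lesion_exon,
             " out of range 1..", n_exons)
    }
  }
  ms
}

#' Read a mutation table from TSV
#'
#' Expected header:
#' `id  mclass  first_exon  last_exon  lesion_site  phenotype  hgvs`
#' with empty cells for inapplicable fields. Small lesions put their exon in
#' `first_exon`. Rows with an `hgvs` cell and empty coordinate cells are
#' routed through [parse_hgvs_lite()].
#'
#' @param path TSV file path.
#' @param t a `transcript_model` (used for HGVS resolution and range checks).
#' @return A validated mutation data frame, one row per record.
#' @export
read_mutation_table <- function(path, t) {
  stopifnot(inherits(t, "transcript_model"))
  if (!file.exists(path)) stop("mutation table not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  need <- c("id", "mclass", "first_exon", "last_exon", "lesion_site",
            "phenotype", "hgvs")
  if (!all(need %in% names(df)))
    stop("mutation TSV must have columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0L)
    return(validate_mutations(data.frame(
      id = character(), mclass = character(), first_exon = integer(),
      last_exon = integer(), lesion_exon = integer(),
      lesion_site = character(), phenotype = character(),
      raw = character(), stringsAsFactors = FALSE), t))
  rows <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    r <- lapply(df[i, ], trimws)
    wrap <- function(expr) tryCatch(expr, error = function(e)
      stop("row ", i, ": ", conditionMessage(e), call. = FALSE))
    if (nzchar(r$hgvs) && !nzchar(r$first_exon)) {
      m <- wrap(parse_hgvs_lite(r$hgvs, t))
      m$id <- r$id
      m$phenotype <- wrap(normalize_phenotype(r$phenotype))
      rows[[i]] <- m
    } else {
      mclass <- tolower(r$mclass)
      if (identical(mclass, "small_lesion")) {
        rows[[i]] <- wrap(mutation(
          r$id, mclass,
          lesion_exon = as_int(r$first_exon, i, "first_exon"),
          lesion_site = r$lesion_site,
          phenotype = r$phenotype,
          raw = if (nzchar(r$hgvs)) r$hgvs else NA, t = t))
      } else {
        rows[[i]] <- wrap(mutation(
          r$id, mclass,
          first_exon = as_int(r$first_exon, i, "first_exon"),
          last_exon = as_int(r$last_exon, i, "last_exon"),
          phenotype = r$phenotype,
          raw = if (nzchar(r$hgvs)) r$hgvs else NA, t = t))
      }
    }
  }
  ms <- do.call(rbind, rows)
  validate_mutations(ms, t)
}

as_int <- function(x, row, field) {
  v <- suppressWarnings(as.integer(x))
  if (is.na(v)) stop("row ", row, ": field ", field,
                     " is not an integer: '", x, "'", call. = FALSE)
  v
}

#' Keep mutations with selected phenotype labels
#'
#' Order-preserving subset. The default keeps only DMD-associated records,
#' the analysis population for exon-skipping applicability.
#'
#' @param ms mutation data frame.
#' @param keep character vector of phenotype labels to keep.
#' @return The subset of `ms`, in the original order.
#' @export
filter_phenotype <- function(ms, keep = "DMD") {
  keep <- normalize_phenotype(keep)
  ms[ms$phenotype %in% keep, , drop = FALSE]
}

#' Write a mutation table to TSV
#'
#' Emits the schema read by [read_mutation_table()], so
#' `read_mutation_table(write_cohort(ms, f), t)` round-trips.
#'
#' @param ms mutation data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(ms, path) {
  stopifnot(is.data.frame(ms))
  out <- data.frame(
    id = ms$id,
    mclass = ms$mclass,
    first_exon = ifelse(ms$mclass == "small_lesion",
                        ms$lesion_exon, ms$first_exon),
    last_exon = ifelse(ms$mclass == "small_lesion", NA, ms$last_exon),
    lesion_site = ms$lesion_site,
    phenotype = ms$phenotype,
    hgvs = ms$raw,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
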