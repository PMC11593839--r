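#' Configuration for the synthetic mutation-cohort generator
#'
#' The generator emulates the composition of the DMD-associated (severe
#' phenotype) records of a locus-specific dystrophin mutation database: the
#' class mix of large deletions, small lesions, and large duplications; the
#' two deletion hotspots (exons 43-55 and exons 2-22); the excess of
#' single-exon duplications and of exon-2 duplication starts; and the share
#' of small lesions at splice sites. Deletions and duplications are drawn
#' conditioned on being frameshift, because under the reading-frame rule only
#' frameshift large rearrangements carry the DMD label and the class mix
#' describes the DMD-labelled cohort; `frame_rule_noise` relaxes the rule.
#'
#' @param n cohort size (>= 0).
#' @param seed RNG seed; generation is deterministic for fixed
#'   (seed, config, transcript).
#' @param class_mix probabilities for (deletion, small_lesion, duplication),
#'   renormalized to sum to 1. Default (0.60, 0.27, 0.135).
#' @param deletion_hotspots list of `list(range = c(first, last), weight = w)`
#'   giving the probability that a deletion is drawn inside each hotspot;
#'   the remaining weight draws a deletion starting outside every hotspot.
#' @param deletion_span_mean mean exon span of deletions (truncated geometric;
#'   spans are cut at the containing region's end).
#' @param dup_single_prob probability a duplication is single-exon
#'   (default 52/232, the single/total split of DMD-labelled duplications).
#' @param dup_exon2_weight sampling-weight multiplier for exon 2 as the
#'   duplication start, making exon-2 duplications the modal duplication.
#' @param splice_fraction fraction of small lesions at splice sites, split
#'   evenly between donor and acceptor.
#' @param frame_rule_noise probability that a record violates the reading-frame
#'   rule: with this probability a deletion/duplication is drawn without the
#'   frameshift condition and any in-frame result keeps the DMD label, and a
#'   frameshift record's label is flipped to BMD.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n = 1000L, seed = 1L,
                             class_mix = c(deletion = 0.60,
                                           small_lesion = 0.27,
                                           duplication = 0.135),
                             deletion_hotspots = list(
                               list(range = c(43L, 55L), weight = 0.70),
                               list(range = c(2L, 22L), weight = 0.21)),
                             deletion_span_mean = 4,
                             dup_single_prob = 52 / 232,
                             dup_exon2_weight = 15,
                             splice_fraction = 0.25,
                             frame_rule_noise = 0) {
  stopifnot(n >= 0, length(class_mix) == 3L, all(class_mix >= 0),
            sum(class_mix) > 0, deletion_span_mean >= 1,
            dup_single_prob >= 0, dup_single_prob <= 1,
            dup_exon2_weight > 0,
            splice_fraction >= 0, splice_fraction <= 1,
            frame_rule_noise >= 0, frame_rule_noise <= 1)
  hw <- vapply(deletion_hotspots, function(h) h$weight, numeric(1))
  if (any(hw < 0) || sum(hw) > 1)
    stop("hotspot weights must be non-negative and sum to at most 1")
  structure(list(
    n = as.integer(n), seed = as.integer(seed),
    class_mix = class_mix / sum(class_mix),
    deletion_hotspots = deletion_hotspots,
    deletion_span_mean = deletion_span_mean,
    dup_single_prob = dup_single_prob,
    dup_exon2_weight = dup_exon2_weight,
    splice_fraction = splice_fraction,
    frame_rule_noise = frame_rule_noise), class = "generator_config")
}

# truncated-geometric exon span with the given mean (support 1, 2, ...)
sample_span <- function(mean_span) {
  if (mean_span <= 1) return(1L)
  1L + stats::rgeom(1L, prob = 1 / mean_span)
}

sample_deletion <- function(t, cfg, require_frameshift) {
  n_ex <- nrow(t)
  hw <- vapply(cfg$deletion_hotspots, function(h) h$weight, numeric(1))
  regions <- lapply(cfg$deletion_hotspots, function(h)
    if (h$range[1] > n_ex) integer(0) else h$range[1]:min(h$range[2], n_ex))
  elsewhere <- setdiff(seq_len(n_ex), unique(unlist(regions)))
  regions <- c(regions, list(elsewhere))
  w <- c(hw, 1 - sum(hw))
  keep <- vapply(regions, length, integer(1)) > 0 & w > 0
  # the region is drawn once so that hotspot shares match the configured
  # weights exactly; frameshift rejection happens within the region
  ri <- which(keep)[sample.int(sum(keep), 1L,
                               prob = w[keep] / sum(w[keep]))]
  reg <- regions[[ri]]
  end_cap <- if (ri <= length(cfg$deletion_hotspots))
    min(cfg$deletion_hotspots[[ri]]$range[2], n_ex) else n_ex
  for (try in 1:500) {
    start <- reg[sample.int(length(reg), 1L)]
    span <- sample_span(cfg$deletion_span_mean)
    last <- min(start + span - 1L, end_cap)
    if (!require_frameshift ||
        deletion_frame_status(t, start, last) == "frameshift")
      return(c(start, last))
  }
  stop("could not draw a frameshift deletion; check the transcript model")
}

sample_duplication <- function(t, cfg, require_frameshift) {
  n_ex <- nrow(t)
  w <- rep(1, n_ex); w[min(2L, n_ex)] <- cfg$dup_exon2_weight
  for (try in 1:200) {
    single <- stats::runif(1) < cfg$dup_single_prob
    start <- sample.int(n_ex, 1L, prob = w)
    last <- if (single) start else
      min(start + 1L + sample_span(cfg$deletion_span_mean - 1), n_ex)
    if (!require_frameshift ||
        deletion_frame_status(t, start, last) == "frameshift")
      return(c(start, last))
  }
  stop("could not draw a frameshift duplication; check the transcript model")
}

sample_small_lesion <- function(t, cfg) {
  n_ex <- nrow(t)
  u <- stats::runif(1)
  site <- if (u < cfg$splice_fraction / 2) "donor"
          else if (u < cfg$splice_fraction) "acceptor"
          else "intra"
  # point mutations accumulate in proportion to exon coding length;
  # a donor site needs a following intron, an acceptor a preceding one
  valid <- switch(site,
                  donor = seq_len(n_ex - 1L),
                  acceptor = seq.int(2L, n_ex),
                  intra = seq_len(n_ex))
  wl <- t$coding_length[valid]
  e <- valid[sample.int(length(valid), 1L, prob = wl)]
  c(e, match(site, LESION_SITES))
}

#' Generate a synthetic DMD-labelled mutation cohort
#'
#' Draws `cfg$n` mutation records emulating the composition of the
#' DMD-associated records of a dystrophin mutation database (see
#' [generator_config()]). Phenotype labels follow the reading-frame rule
#' (frameshift deletions/duplications and all small lesions are DMD); with
#' probability `frame_rule_noise` a record violates the rule (an in-frame
#' rearrangement labelled DMD, or a frameshift one labelled BMD). Output is
#' deterministic for fixed (seed, config, transcript) and leaves the caller's
#' RNG state untouched.
#'
#' @param t a `transcript_model`.
#' @param cfg a [generator_config()].
#' @return A validated mutation data frame with `cfg$n` rows (ids
#'   `"sim00001"`, ...).
#' @export
generate_cohort <- function(t, cfg = generator_config()) {
  stopifnot(inherits(t, "transcript_model"),
            inherits(cfg, "generator_config"))
  if (cfg$n == 0L) {
    return(validate_mutations(data.frame(
      id = character(), mclass = character(), first_exon = integer(),
      last_exon = integer(), lesion_exon = integer(),
      lesion_site = character(), phenotype = character(),
      raw = character(), stringsAsFactors = FALSE), t))
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(cfg$seed)

  cls <- c("deletion", "small_lesion", "duplication")
  classes <- sample(cls, cfg$n, replace = TRUE,
                    prob = cfg$class_mix[cls])
  rows <- vector("list", cfg$n)
  for (i in seq_len(cfg$n)) {
    id <- sprintf("sim%05d", i)
    violate <- stats::runif(1) < cfg$frame_rule_noise
    cl <- classes[i]
    if (cl == "small_lesion") {
      sl <- sample_small_lesion(t, cfg)
      rows[[i]] <- data.frame(
        id = id, mclass = cl, first_exon = NA_integer_,
        last_exon = NA_integer_, lesion_exon = sl[1],
        lesion_site = LESION_SITES[sl[2]], phenotype = "DMD",
        raw = NA_character_, stringsAsFactors = FALSE)
    } else {
      rng <- if (cl == "deletion")
        sample_deletion(t, cfg, require_frameshift = !violate)
      else sample_duplication(t, cfg, require_frameshift = !violate)
      fs <- deletion_frame_status(t, rng[1], rng[2]) == "frameshift"
      # rule label, flipped for rule-violating records
      pheno <- if (fs) "DMD" else "BMD"
      if (violate) pheno <- if (fs) "BMD" else "DMD"
      rows[[i]] <- data.frame(
        id = id, mclass = cl, first_exon = rng[1], last_exon = rng[2],
        lesion_exon = NA_integer_, lesion_site = NA_character_,
        phenotype = pheno, raw = NA_character_, stringsAsFactors = FALSE)
    }
  }
  validate_mutations(do.call(rbind, rows), t)
}
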