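# Survey-level workflow: given a table of per-species profiles, select
# taxonomic groups and compute the standard statistics of a microsatellite
# survey (group Wilcoxon tests, composition counts, GC correlations, and
# Moran's I for a user-supplied clade pooling).

#' Construct a clade partition directly
#'
#' For poolings not derived from a tree (e.g. taxonomic groups standing in
#' for clades at a known age cutoff).
#'
#' @param clade_of Named integer (or factor) vector mapping species id to
#'   clade index.
#' @param cutoff_mya Optional age cutoff the pooling corresponds to.
#' @return A `clade_partition` usable with [morans_i()].
#' @export
clade_partition <- function(clade_of, cutoff_mya = NA_real_) {
  if (is.null(names(clade_of)) || any(names(clade_of) == ""))
    stop("clade_of must be named by species id", call. = FALSE)
  idx <- as.integer(as.factor(clade_of))
  structure(list(cutoff_mya = cutoff_mya,
                 clade_of = stats::setNames(idx, names(clade_of)),
                 n_clades = length(unique(idx))),
            class = "clade_partition")
}

#' Select species whose taxonomy matches a pattern
#'
#' Case-insensitive regular-expression match against the concatenated
#' taxonomy labels (and the species id itself).
#'
#' @param profiles List of `species_profile` objects.
#' @param pattern Regular expression, e.g. `"Streptophyta"` or
#'   `"Actinopter"`.
#' @return Character vector of matching species ids.
#' @export
group_species <- function(profiles, pattern) {
  hit <- vapply(profiles, function(p)
    grepl(pattern, paste(c(p$species_id, p$taxonomy), collapse = " "),
          ignore.case = TRUE), logical(1))
  vapply(profiles[hit], `[[`, character(1), "species_id")
}

#' Coverage vector over a set of profiles
#'
#' @param profiles List of `species_profile` objects.
#' @param include_homopolymers Passed to [total_coverage()].
#' @return Named numeric vector of coverages (bases/Mb) by species id.
#' @export
coverage_vector <- function(profiles, include_homopolymers = FALSE) {
  stats::setNames(
    vapply(profiles, total_coverage,
           include_homopolymers = include_homopolymers, numeric(1)),
    vapply(profiles, `[[`, character(1), "species_id"))
}

# per-profile value extractors used by survey_statistics
.motif_prop_of <- function(p, k, motif) {
  mp <- suppressWarnings(motif_proportions(p, k))
  if (length(mp) == 0L) return(NA_real_)
  unname(mp[[motif]])
}

#' Survey statistics for a set of species profiles
#'
#' Computes, from per-species profiles and named species groups, the
#' statistics reported by a comparative microsatellite survey: Wilcoxon
#' rank-sum coverage comparisons between groups (both orientations of W are
#' returned, since W depends on which sample is named first), Spearman
#' correlations of A/T-rich repeat proportions against GC content,
#' composition head-counts, and Moran's I for a clade pooling of the plant
#' species at the 200 Mya level (flowering plants | conifers | cycads).
#'
#' @param profiles List of `species_profile` objects.
#' @param groups Named list of species-id character vectors with entries
#'   `plants`, `actinopterygii`, `tetrapods`, `magnoliophyta`,
#'   `coniferophyta`, `cycadophyta` (missing entries skip the dependent
#'   statistics).  See [default_survey_groups()].
#' @return A list of statistics; `NULL` entries mark statistics whose
#'   groups were not supplied.
#' @export
survey_statistics <- function(profiles, groups = default_survey_groups(profiles)) {
  cov <- coverage_vector(profiles)
  all_sp <- names(cov)
  out <- list(n_species = length(profiles))
  wtest <- function(g1, g2)
    list(forward = wilcoxon_rank_sum(cov[g1], cov[g2]),
         reverse = wilcoxon_rank_sum(cov[g2], cov[g1]))
  if (!is.null(groups$plants) && length(groups$plants)) {
    animals <- setdiff(all_sp, groups$plants)
    out$wilcoxon_plants_vs_animals <- wtest(groups$plants, animals)
  }
  if (!is.null(groups$actinopterygii) && !is.null(groups$tetrapods))
    out$wilcoxon_actinopterygii_vs_tetrapods <-
      wtest(groups$actinopterygii, groups$tetrapods)
  conif_cycad <- c(groups$coniferophyta, groups$cycadophyta)
  if (!is.null(groups$magnoliophyta) && length(conif_cycad))
    out$wilcoxon_magnoliophyta_vs_other_seed_plants <-
      wtest(groups$magnoliophyta, conif_cycad)
  # GC correlations of A/T-rich repeat proportions
  gc <- vapply(profiles, `[[`, numeric(1), "gc_fraction")
  poly_at <- vapply(profiles, .motif_prop_of, numeric(1), 1L, "A")
  at_prop <- vapply(profiles, .motif_prop_of, numeric(1), 2L, "AT")
  safe_rho <- function(a, b) {
    keep <- !is.na(a)
    if (sum(keep) < 3) return(NULL)
    tryCatch(spearman_rho(a[keep], b[keep]), error = function(e) NULL)
  }
  out$spearman_polyAT_vs_gc <- safe_rho(poly_at, gc)
  out$spearman_AT_vs_gc <- safe_rho(at_prop, gc)
  # composition head-counts over di-hexa microsatellite bases
  unit_bases <- t(vapply(profiles, function(p) {
    u <- nchar(names(p$bases_by_motif))
    vapply(2:6, function(k) sum(p$bases_by_motif[u == k]), numeric(1))
  }, numeric(5)))
  nonzero <- rowSums(unit_bases) > 0
  out$n_dinucleotide_most_frequent <-
    sum(nonzero & max.col(unit_bases, ties.method = "first") == 1L &
          unit_bases[, 1] > 0)
  out$n_dinucleotide_majority <-
    sum(unit_bases[, 1] > rowSums(unit_bases[, -1, drop = FALSE]))
  aat <- vapply(profiles, .motif_prop_of, numeric(1), 3L, "AAT")
  out$n_AAT_proportion_above_0.1 <- sum(!is.na(aat) & aat > 0.1)
  # Moran's I for the plant pooling at the 200 Mya level
  if (!is.null(groups$magnoliophyta) && length(conif_cycad)) {
    cl <- c(stats::setNames(rep(1L, length(groups$magnoliophyta)),
                            groups$magnoliophyta),
            stats::setNames(rep(2L, length(groups$coniferophyta)),
                            groups$coniferophyta),
            stats::setNames(rep(3L, length(groups$cycadophyta)),
                            groups$cycadophyta))
    part <- clade_partition(cl, cutoff_mya = 200)
    out$moran_plants_200 <- tryCatch(morans_i(log(cov[names(cl)]), part),
                                     error = function(e) NULL)
  }
  out
}

#' Infer standard survey groups from profile taxonomies
#'
#' Pattern-matches taxonomy labels: plants are Streptophyta; ray-finned
#' fishes match `Actinopter` (covering both common spellings); tetrapods
#' are the union of Amphibia, Aves, Mammalia, Squamata, Testudines and
#' Crocodylia; seed-plant divisions match their division names.
#'
#' @param profiles List of `species_profile` objects.
#' @return Named list of species-id vectors (entries may be empty).
#' @export
default_survey_groups <- function(profiles) {
  list(plants = group_species(profiles, "Streptophyta"),
       actinopterygii = group_species(profiles, "Actinopter"),
       tetrapods = unique(unlist(lapply(
         c("Amphibia", "Aves", "Mammalia", "Squamata", "Testudines",
           "Crocodylia"),
         function(tk) group_species(profiles, tk)))),
       magnoliophyta = group_species(profiles, "Magnoliophyta"),
       coniferophyta = group_species(profiles, "Conifero"),
       cycadophyta = group_species(profiles, "Cycad"))
}
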