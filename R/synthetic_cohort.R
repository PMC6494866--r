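#' Specification of a synthetic two-cohort study
#'
#' Defines the generative model used throughout testing and power analysis:
#' a geometric rank-abundance genus profile, Dirichlet-multinomial
#' overdispersion, log-normal sequencing depth with an optional low-depth
#' failure fraction, a dysbiotic case subpopulation produced by depleting a
#' set of moderately abundant genera, and clinical covariates whose odds
#' differ between latent classes.
#'
#' Defaults mirror a duodenal-aspirate study design: 38 reference (healthy)
#' samples versus 126 symptomatic cases over 65 genera.  The dysbiotic
#' class depletes the 20 genera at abundance ranks 6-25 to 10% of their
#' reference mean — dysbiosis in these communities manifests mostly as the
#' relative absence of a block of moderately abundant genera — which lowers
#' alpha diversity in the affected samples.
#'
#' @param n_reference Number of reference (healthy) samples.
#' @param n_case Number of symptomatic case samples.
#' @param n_taxa Number of genera.
#' @param base_decay Geometric rank-abundance decay rate in (0,1).
#' @param dispersion Dirichlet-multinomial overdispersion theta (> 0); the
#'   Dirichlet concentration is `mean/theta`, so larger theta means more
#'   between-sample variability.
#' @param depth_meanlog,depth_sdlog Log-normal read-depth parameters
#'   (natural log scale); defaults give a median of 20,000 reads.
#' @param low_depth_fraction Fraction of samples whose depth is replaced by
#'   a uniform draw on 100-999 reads, emulating failed libraries.
#' @param differential_taxa Integer abundance ranks depleted in the
#'   dysbiotic class.
#' @param fold_change Multiplicative fold change(s) applied to
#'   `differential_taxa` (recycled; must be > 0).
#' @param dysbiotic_fraction Proportion of cases drawn from the depleted
#'   distribution.
#' @param covariate_model List of covariate prevalences and class-linked
#'   odds multipliers; see [simulate_covariates()].
#' @param seed Integer master seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_reference = 38, n_case = 126, n_taxa = 65,
                        base_decay = 0.85, dispersion = 0.02,
                        depth_meanlog = log(20000), depth_sdlog = 0.5,
                        low_depth_fraction = 0.05,
                        differential_taxa = 6:25, fold_change = 0.1,
                        dysbiotic_fraction = 0.3,
                        covariate_model = default_covariate_model(),
                        seed = 1L) {
  stopifnot(n_reference >= 1, n_case >= 1, n_taxa >= 2,
            base_decay > 0, base_decay < 1, dispersion > 0,
            low_depth_fraction >= 0, low_depth_fraction <= 1,
            dysbiotic_fraction >= 0, dysbiotic_fraction <= 1,
            all(fold_change > 0),
            all(differential_taxa >= 1), all(differential_taxa <= n_taxa))
  structure(list(n_reference = n_reference, n_case = n_case,
                 n_taxa = n_taxa, base_decay = base_decay,
                 dispersion = dispersion, depth_meanlog = depth_meanlog,
                 depth_sdlog = depth_sdlog,
                 low_depth_fraction = low_depth_fraction,
                 differential_taxa = as.integer(differential_taxa),
                 fold_change = fold_change,
                 dysbiotic_fraction = dysbiotic_fraction,
                 covariate_model = covariate_model,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default clinical covariate model
#'
#' Baseline prevalences for the healthy-like class and odds multipliers for
#' the dysbiotic class, chosen to resemble a tertiary-care SIBO-workup
#' population: frequent PPI use and recent antibiotics, less frequent GI
#' surgery, adult ages spanning 18-89 years with dysbiotic patients older
#' on average.
#'
#' @return A list with elements `prevalence` (named baseline prevalences),
#'   `odds_multiplier` (named, same covariates), `age_range`,
#'   `age_dysbiosis_shift` (years), `female_prevalence`, `bmi_mean`,
#'   `bmi_sd`, and `sibo_meanlog10` (healthy-like and dysbiotic mean log10
#'   CFU/mL, SD 1).
#' @export
default_covariate_model <- function() {
  list(prevalence = c(antibiotics_recent = 0.25, ppi = 0.35,
                      gi_surgery = 0.15),
       odds_multiplier = c(antibiotics_recent = 3, ppi = 2, gi_surgery = 2),
       age_range = c(18, 89),
       age_dysbiosis_shift = 10,
       female_prevalence = 0.55,
       bmi_mean = 27, bmi_sd = 5,
       sibo_meanlog10 = c(3.5, 5))
}

#' Geometric rank-abundance profile
#'
#' @param n_taxa Number of taxa.
#' @param decay Geometric decay rate in (0,1).
#' @return A simplex vector, most abundant taxon first.
#' @export
rank_abundance_profile <- function(n_taxa, decay = 0.85) {
  stopifnot(n_taxa >= 1, decay > 0, decay < 1)
  p <- decay^(seq_len(n_taxa) - 1)
  p / sum(p)
}

#' Draw Dirichlet-multinomial count samples
#'
#' Each sample's composition is drawn from a Dirichlet with concentration
#' `mean_proportions / dispersion`, then reads are drawn multinomially at
#' the requested depth.  Column sums equal the requested depths exactly.
#'
#' @param mean_proportions Simplex vector of expected proportions.
#' @param dispersion Overdispersion theta (> 0); the Dirichlet total
#'   concentration is `1/theta`.
#' @param depth Read depth, scalar or one value per sample.
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return Integer matrix, taxa x n.
#' @export
simulate_dirichlet_multinomial <- function(mean_proportions, dispersion,
                                           depth, n, seed) {
  k <- length(mean_proportions)
  if (k == 0L) stop_input("mean_proportions is empty")
  stopifnot(all(mean_proportions >= 0), dispersion > 0, n >= 1)
  if (abs(sum(mean_proportions) - 1) > 1e-8)
    stop_input("mean_proportions must sum to 1")
  depth <- rep_len(depth, n)
  alpha <- mean_proportions / dispersion
  with_seed(seed, {
    out <- matrix(0, nrow = k, ncol = n)
    for (j in seq_len(n)) {
      g <- rgamma(k, shape = alpha, rate = 1)
      if (sum(g) == 0) g[which.max(alpha)] <- 1  # numeric underflow guard
      out[, j] <- rmultinom(1L, size = depth[j], prob = g / sum(g))
    }
    out
  })
}

#' Deplete (or enrich) selected taxa in a mean-proportion vector
#'
#' Targeted components are multiplied by their fold change and the vector
#' is renormalized back onto the simplex.
#'
#' @param mean_proportions Simplex vector.
#' @param differential_taxa Indices (abundance ranks) to modify.
#' @param fold_changes Positive fold change(s), recycled over the targets;
#'   values below 1 deplete.
#' @return The renormalized simplex vector.
#' @export
inject_differential_effect <- function(mean_proportions, differential_taxa,
                                       fold_changes) {
  if (any(fold_changes <= 0)) stop_input("fold changes must be > 0")
  stopifnot(all(differential_taxa >= 1),
            all(differential_taxa <= length(mean_proportions)))
  p <- mean_proportions
  p[differential_taxa] <- p[differential_taxa] *
    rep_len(fold_changes, length(differential_taxa))
  p / sum(p)
}

#' Simulate clinical covariates, optionally linked to a latent class
#'
#' Binary covariates are Bernoulli at the model's baseline prevalence for
#' healthy-like samples; for dysbiotic samples the odds are multiplied by
#' the model's odds multiplier.  Age is uniform on `age_range` with a mean
#' shift for dysbiotic samples (truncated to the range); sex and BMI are
#' class-independent.  SIBO culture results are log10-normal with a higher
#' mean in the dysbiotic class.
#'
#' @param n Number of samples.
#' @param covariate_model See [default_covariate_model()].
#' @param dysbiotic Logical vector of latent class (default all `FALSE`).
#' @param seed Integer seed.
#' @return A data frame (no `sample_id`/`group`; the caller adds those).
#' @export
simulate_covariates <- function(n, covariate_model = default_covariate_model(),
                                dysbiotic = rep(FALSE, n), seed = 1L) {
  cm <- covariate_model
  stopifnot(all(cm$prevalence >= 0), all(cm$prevalence <= 1),
            length(dysbiotic) == n)
  with_seed(seed, {
    age <- runif(n, cm$age_range[1], cm$age_range[2]) +
      ifelse(dysbiotic, cm$age_dysbiosis_shift, 0)
    age <- pmin(age, cm$age_range[2])
    md <- data.frame(
      age = round(age, 1),
      sex = ifelse(runif(n) < cm$female_prevalence, "F", "M"),
      bmi = round(rnorm(n, cm$bmi_mean, cm$bmi_sd), 1),
      stringsAsFactors = FALSE)
    for (cov in names(cm$prevalence)) {
      p0 <- cm$prevalence[[cov]]
      mult <- cm$odds_multiplier[[cov]] %||% 1
      odds <- p0 / (1 - p0) * ifelse(dysbiotic, mult, 1)
      md[[cov]] <- runif(n) < odds / (1 + odds)
    }
    mu <- ifelse(dysbiotic, cm$sibo_meanlog10[2], cm$sibo_meanlog10[1])
    md$sibo_cfu <- signif(10^rnorm(n, mu, 1), 3)
    md$indication <- sample(c("bloating", "diarrhea", "pain", "nausea"),
                            n, replace = TRUE)
    md
  })
}

#' Simulate a random rooted phylogeny over a set of taxa
#'
#' A random bifurcating rooted topology with exponential branch lengths
#' (mean 0.1), suitable for Faith's PD and UniFrac on synthetic cohorts.
#'
#' @param taxon_ids Tip labels (>= 2).
#' @param seed Integer seed.
#' @return An [ape::phylo] tree.
#' @export
simulate_tree <- function(taxon_ids, seed = 1L) {
  n <- length(taxon_ids)
  if (n < 2L) stop_input("need at least 2 taxa for a tree")
  with_seed(seed, {
    ape::rtree(n, tip.label = sample(taxon_ids),
               br = function(k) rexp(k, rate = 10))
  })
}

#' Generate a complete synthetic cohort with recorded ground truth
#'
#' Reference samples are drawn from the base rank-abundance distribution;
#' a fixed fraction of cases (rounded) is drawn from the depleted
#' distribution and the rest from the base distribution.  Covariates are
#' linked to the latent class, a random phylogeny is attached, and the
#' latent class plus per-taxon true fold changes are recorded.
#'
#' @param spec A [cohort_spec].
#' @return A list of class `synthetic_cohort` with elements `table`
#'   ([count_table]), `metadata` (data frame), `tree` ([ape::phylo]),
#'   `truth` (list with `sample_class` data frame and `taxon_fold_change`
#'   vector), and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  k <- spec$n_taxa
  base <- rank_abundance_profile(k, spec$base_decay)
  shifted <- inject_differential_effect(base, spec$differential_taxa,
                                        spec$fold_change)
  taxa <- sprintf("Genus%03d", seq_len(k))

  n_ref <- spec$n_reference
  n_case <- spec$n_case
  n_dys <- round(spec$dysbiotic_fraction * n_case)
  dys_case <- with_seed(derive_seed(spec$seed, "latent"), {
    x <- rep(FALSE, n_case)
    x[sample.int(n_case, n_dys)] <- TRUE
    x
  })

  depths <- with_seed(derive_seed(spec$seed, "depths"), {
    d <- round(exp(rnorm(n_ref + n_case, spec$depth_meanlog,
                         spec$depth_sdlog)))
    shallow <- runif(n_ref + n_case) < spec$low_depth_fraction
    d[shallow] <- round(runif(sum(shallow), 100, 999))
    pmax(d, 10)
  })

  ref_counts <- simulate_dirichlet_multinomial(
    base, spec$dispersion, depths[seq_len(n_ref)], n_ref,
    derive_seed(spec$seed, "reference"))
  case_depths <- depths[n_ref + seq_len(n_case)]
  case_counts <- matrix(0, nrow = k, ncol = n_case)
  if (any(!dys_case))
    case_counts[, !dys_case] <- simulate_dirichlet_multinomial(
      base, spec$dispersion, case_depths[!dys_case], sum(!dys_case),
      derive_seed(spec$seed, "case_base"))
  if (any(dys_case))
    case_counts[, dys_case] <- simulate_dirichlet_multinomial(
      shifted, spec$dispersion, case_depths[dys_case], sum(dys_case),
      derive_seed(spec$seed, "case_dysbiotic"))

  counts <- cbind(ref_counts, case_counts)
  sample_ids <- c(sprintf("H%03d", seq_len(n_ref)),
                  sprintf("P%03d", seq_len(n_case)))
  dimnames(counts) <- list(taxa, sample_ids)

  taxonomy <- with_seed(derive_seed(spec$seed, "taxonomy"), {
    fam <- sprintf("Family%02d", sample.int(max(2L, k %/% 5L), k,
                                            replace = TRUE))
    phy <- sprintf("Phylum%d", sample.int(4L, k, replace = TRUE))
    cbind(kingdom = "Bacteria", phylum = phy,
          class = paste0(phy, "_c"), order = paste0(fam, "_o"),
          family = fam, genus = taxa)
  })
  rownames(taxonomy) <- taxa

  dysbiotic <- c(rep(FALSE, n_ref), dys_case)
  covars <- simulate_covariates(n_ref + n_case, spec$covariate_model,
                                dysbiotic,
                                derive_seed(spec$seed, "covariates"))
  metadata <- cbind(
    data.frame(sample_id = sample_ids,
               group = c(rep("healthy", n_ref), rep("symptomatic", n_case)),
               stringsAsFactors = FALSE),
    covars)

  fold <- rep(1, k)
  fold[spec$differential_taxa] <- rep_len(spec$fold_change,
                                          length(spec$differential_taxa))
  names(fold) <- taxa

  structure(list(
    table = count_table(counts, taxonomy = taxonomy),
    metadata = metadata,
    tree = simulate_tree(taxa, derive_seed(spec$seed, "tree")),
    truth = list(
      sample_class = data.frame(
        sample_id = sample_ids,
        latent_class = ifelse(dysbiotic, "dysbiotic", "healthy-like"),
        stringsAsFactors = FALSE),
      taxon_fold_change = fold),
    spec = spec), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", x$spec$n_reference, "reference +",
      x$spec$n_case, "case samples,", x$spec$n_taxa, "genera\n")
  cat("  dysbiotic cases:",
      sum(x$truth$sample_class$latent_class == "dysbiotic"), "\n")
  invisible(x)
}
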