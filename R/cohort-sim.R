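#' Specify a synthetic postmortem cohort
#'
#' Describes a two- (or more-) group case-control cohort of brain-tissue
#' donors with the demographic and peri-mortem covariates that matter for
#' postmortem expression work: age, sex, hemisphere, postmortem interval
#' (PMI, hours), tissue pH, smoking and suicide status. Defaults reproduce
#' the covariate structure of a combined schizophrenia brain-bank cohort
#' (71 unaffected controls, 72 cases; age about 47 +/- 12 years; pH about
#' 6.6 +/- 0.28; PMI about 27-30 +/- 12-15 h; smoking and suicide strongly
#' group-dependent).
#'
#' Every distribution parameter may be a single value (shared by all groups)
#' or a named vector with one entry per group.
#'
#' @param n_per_group named integer vector: samples per diagnostic group.
#' @param age_mean,age_sd age distribution (years).
#' @param pmi_mean,pmi_sd postmortem interval distribution (hours).
#' @param ph_mean,ph_sd tissue pH distribution.
#' @param prop_male,prop_left proportion male / left hemisphere.
#' @param prop_smoker,prop_suicide group-conditional probabilities of
#'   smoking at death and death by suicide.
#' @return An object of class \code{cohort_spec}.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_per_group = c(control = 71, schizophrenia = 72),
                        age_mean = c(control = 47.6, schizophrenia = 47.1),
                        age_sd = c(control = 12.2, schizophrenia = 12.5),
                        pmi_mean = c(control = 27.04, schizophrenia = 29.89),
                        pmi_sd = c(control = 12.15, schizophrenia = 14.63),
                        ph_mean = c(control = 6.64, schizophrenia = 6.55),
                        ph_sd = 0.28,
                        prop_male = c(control = 55 / 71, schizophrenia = 50 / 72),
                        prop_left = c(control = 30 / 71, schizophrenia = 37 / 72),
                        prop_smoker = c(control = 18 / 39, schizophrenia = 46 / 57),
                        prop_suicide = c(control = 0, schizophrenia = 15 / 72)) {
  check_that(length(n_per_group) >= 1 && !is.null(names(n_per_group)),
             "n_per_group", "must be a named vector of group sizes")
  check_that(all(n_per_group >= 2), "n_per_group", "each group needs n >= 2")
  groups <- names(n_per_group)
  spec <- list(
    n_per_group = n_per_group,
    groups = groups,
    age_mean = per_group(age_mean, groups, "age_mean"),
    age_sd = per_group(age_sd, groups, "age_sd"),
    pmi_mean = per_group(pmi_mean, groups, "pmi_mean"),
    pmi_sd = per_group(pmi_sd, groups, "pmi_sd"),
    ph_mean = per_group(ph_mean, groups, "ph_mean"),
    ph_sd = per_group(ph_sd, groups, "ph_sd"),
    prop_male = per_group(prop_male, groups, "prop_male"),
    prop_left = per_group(prop_left, groups, "prop_left"),
    prop_smoker = per_group(prop_smoker, groups, "prop_smoker"),
    prop_suicide = per_group(prop_suicide, groups, "prop_suicide")
  )
  for (f in c("age_sd", "pmi_sd", "ph_sd"))
    check_that(all(spec[[f]] > 0), f, "standard deviations must be > 0")
  for (f in c("prop_male", "prop_left", "prop_smoker", "prop_suicide"))
    check_that(all(spec[[f]] >= 0 & spec[[f]] <= 1), f,
               "proportions must lie in [0, 1]")
  structure(spec, class = "cohort_spec")
}

#' Generate a synthetic sample manifest
#'
#' Draws one donor record per sample: continuous covariates from normal
#' distributions, categorical ones from group-conditional Bernoulli draws
#' (smoking and suicide depend strongly on diagnosis, as real cohorts show).
#' Covariates are sampled independently of one another within a group.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed; the same spec and seed give an identical manifest.
#' @return A data.frame with columns \code{sample_id}, \code{group},
#'   \code{age}, \code{sex}, \code{hemisphere}, \code{pmi}, \code{ph},
#'   \code{smoker}, \code{suicide}.
#' @examples
#' cohort <- generate_cohort(cohort_spec(), seed = 1)
#' table(cohort$group)
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = NULL) {
  if (!inherits(spec, "cohort_spec")) spec <- do.call(cohort_spec, spec)
  with_seed(seed, {
    rows <- lapply(spec$groups, function(g) {
      n <- spec$n_per_group[[g]]
      data.frame(
        sample_id = sprintf("%s_%03d", g, seq_len(n)),
        group = g,
        age = rnorm(n, spec$age_mean[[g]], spec$age_sd[[g]]),
        sex = ifelse(runif(n) < spec$prop_male[[g]], "male", "female"),
        hemisphere = ifelse(runif(n) < spec$prop_left[[g]], "left", "right"),
        pmi = rnorm(n, spec$pmi_mean[[g]], spec$pmi_sd[[g]]),
        ph = rnorm(n, spec$ph_mean[[g]], spec$ph_sd[[g]]),
        smoker = runif(n) < spec$prop_smoker[[g]],
        suicide = runif(n) < spec$prop_suicide[[g]],
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
}

#' Specify a synthetic gene's expression model
#'
#' A gene's per-sample log2 relative quantity is modelled as a normal "core"
#' plus three optional structures seen in case-control cortical expression
#' data: an additive diagnostic-group shift, a linear coupling to tissue pH
#' calibrated to a target correlation, and a sparse high-expressor
#' subpopulation displaced upwards by a fixed number of core standard
#' deviations (default 5, i.e. unambiguously outside the core). Defaults
#' emulate a pro-apoptotic ligand transcript with a pH correlation of
#' about -0.48 and high-expressor prevalence of 13% in controls versus 32%
#' in cases.
#'
#' @param name gene label.
#' @param core_mean,core_sd location and scale of the normal core on the
#'   log2 relative-quantity scale; \code{core_sd} is the residual SD after
#'   the pH term, so the subpopulation displacement is measured against it.
#' @param subpop_shift_sd displacement of the high-expressor subpopulation,
#'   in units of \code{core_sd}.
#' @param subpop_prevalence probability of subpopulation membership; scalar
#'   or named per group.
#' @param ph_coupling target Pearson correlation between log2 expression and
#'   tissue pH, in (-1, 1).
#' @param group_effect additive shift of the core mean; scalar or named per
#'   group (log2 units).
#' @return An object of class \code{gene_spec}.
#' @export
gene_spec <- function(name,
                      core_mean = 0,
                      core_sd = 0.5,
                      subpop_shift_sd = 5,
                      subpop_prevalence = c(control = 0.13, schizophrenia = 0.32),
                      ph_coupling = -0.48,
                      group_effect = 0) {
  check_that(is.character(name) && length(name) == 1L, "name",
             "must be a single gene label")
  check_that(core_sd > 0, "core_sd", "must be > 0")
  check_that(all(subpop_prevalence >= 0 & subpop_prevalence <= 1),
             "subpop_prevalence", "must lie in [0, 1]")
  check_that(abs(ph_coupling) < 1, "ph_coupling", "must satisfy |rho| < 1")
  structure(list(name = name, core_mean = core_mean, core_sd = core_sd,
                 subpop_shift_sd = subpop_shift_sd,
                 subpop_prevalence = subpop_prevalence,
                 ph_coupling = ph_coupling, group_effect = group_effect),
            class = "gene_spec")
}

#' Generate true per-sample expression values
#'
#' For each gene and sample the log2 relative quantity is
#' \code{core_mean + group_effect + b * (ph - mean(ph)) + e + s}, where
#' \code{e ~ N(0, core_sd^2)}, \code{b} is calibrated so the induced Pearson
#' correlation with pH equals \code{ph_coupling}
#' (\code{b = rho / sqrt(1 - rho^2) * core_sd / sd(ph)}), and \code{s} is
#' \code{subpop_shift_sd * core_sd} with probability
#' \code{subpop_prevalence} (else 0). The subpopulation displacement is
#' applied after the pH term, so the quoted SD distance refers to the core
#' residual scale. Values are returned on the linear 2^x relative-quantity
#' scale (all positive), with the ground-truth subpopulation flag retained.
#'
#' @param cohort a manifest from [generate_cohort()]; must contain
#'   \code{sample_id}, \code{group} and a finite \code{ph} for every sample.
#' @param genes a [gene_spec()] or list of them.
#' @param seed integer seed.
#' @return A long data.frame: \code{sample_id}, \code{group}, \code{gene},
#'   \code{log2_rq}, \code{rq}, \code{is_subpop}.
#' @export
generate_expression <- function(cohort, genes, seed = NULL) {
  if (inherits(genes, "gene_spec")) genes <- list(genes)
  stopifnot(is.data.frame(cohort),
            all(c("sample_id", "group", "ph") %in% names(cohort)))
  check_that(all(is.finite(cohort$ph)), "ph",
             "every sample needs a finite tissue pH")
  groups <- unique(cohort$group)
  n <- nrow(cohort)
  ph_c <- cohort$ph - mean(cohort$ph)
  s_ph <- stats::sd(cohort$ph)
  with_seed(seed, {
    per_gene <- lapply(genes, function(gs) {
      prev <- per_group(gs$subpop_prevalence, groups, "subpop_prevalence")
      geff <- per_group(gs$group_effect, groups, "group_effect")
      rho <- gs$ph_coupling
      b <- if (rho == 0 || s_ph == 0) 0 else
        rho / sqrt(1 - rho^2) * gs$core_sd / s_ph
      is_sub <- runif(n) < prev[cohort$group]
      log2v <- gs$core_mean + unname(geff[cohort$group]) + b * ph_c +
        rnorm(n, 0, gs$core_sd) +
        ifelse(is_sub, gs$subpop_shift_sd * gs$core_sd, 0)
      data.frame(sample_id = cohort$sample_id, group = cohort$group,
                 gene = gs$name, log2_rq = log2v, rq = 2^log2v,
                 is_subpop = is_sub, stringsAsFactors = FALSE)
    })
    do.call(rbind, c(per_gene, list(make.row.names = FALSE)))
  })
}

#' Specify replicate-level Ct measurement noise
#'
#' @param replicate_sd SD of technical replicate noise, in Ct cycles
#'   (instrument precision; 0 gives noiseless plates).
#' @param aberrant_rate probability, per replicate, of an aberrant
#'   displacement (pipetting error, evaporation).
#' @param aberrant_shift magnitude of the aberrant displacement, Ct cycles;
#'   must exceed 3 x \code{replicate_sd} so aberrant replicates are
#'   separable from noise.
#' @param housekeeper_baseline named vector of mean Ct per housekeeper gene;
#'   at least three housekeepers, as geometric-mean normalization requires.
#' @return An object of class \code{ct_noise_spec}.
#' @export
ct_noise_spec <- function(replicate_sd = 0.15,
                          aberrant_rate = 0.02,
                          aberrant_shift = 2,
                          housekeeper_baseline = c(ACTB = 18, TBP = 28, UBC = 22)) {
  check_that(replicate_sd >= 0, "replicate_sd", "must be >= 0")
  check_that(aberrant_rate >= 0 && aberrant_rate < 1, "aberrant_rate",
             "must lie in [0, 1)")
  if (aberrant_rate > 0)
    check_that(aberrant_shift > 3 * replicate_sd, "aberrant_shift",
               "must exceed 3 x replicate_sd")
  check_that(length(housekeeper_baseline) >= 3 &&
               !is.null(names(housekeeper_baseline)),
             "housekeeper_baseline",
             "needs >= 3 named housekeeper genes (geomean of three required)")
  structure(list(replicate_sd = replicate_sd, aberrant_rate = aberrant_rate,
                 aberrant_shift = aberrant_shift,
                 housekeeper_baseline = housekeeper_baseline),
            class = "ct_noise_spec")
}

#' Generate a raw Ct plate from true expression values
#'
#' Emits triplicate Ct measurements per sample x gene. Housekeeper
#' replicates scatter around their baseline Ct; a target gene's replicates
#' scatter around the geometric mean of the housekeeper baselines minus
#' log2 of the sample's true relative quantity, so that delta-delta Ct
#' quantification recovers the planted values. Aberrant replicates are
#' displaced by \code{aberrant_shift} Ct in a random direction at rate
#' \code{aberrant_rate}.
#'
#' @param expression output of [generate_expression()].
#' @param noise a [ct_noise_spec()].
#' @param seed integer seed.
#' @return A long data.frame: \code{sample_id}, \code{gene},
#'   \code{replicate_index}, \code{ct}, \code{is_housekeeper},
#'   \code{is_aberrant} (ground truth).
#' @export
generate_ct_table <- function(expression, noise = ct_noise_spec(), seed = NULL) {
  if (!inherits(noise, "ct_noise_spec")) noise <- do.call(ct_noise_spec, noise)
  stopifnot(is.data.frame(expression),
            all(c("sample_id", "gene", "log2_rq") %in% names(expression)))
  hk <- noise$housekeeper_baseline
  hk_geo <- geomean(hk)
  samples <- unique(expression$sample_id)
  hk_grid <- expand.grid(sample_id = samples, gene = names(hk),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  hk_grid$base_ct <- unname(hk[hk_grid$gene])
  hk_grid$is_housekeeper <- TRUE
  tg_grid <- expression[, c("sample_id", "gene")]
  tg_grid$base_ct <- hk_geo - expression$log2_rq
  tg_grid$is_housekeeper <- FALSE
  grid <- rbind(hk_grid, tg_grid)
  with_seed(seed, {
    reps <- grid[rep(seq_len(nrow(grid)), each = 3L), ]
    reps$replicate_index <- rep(1:3, nrow(grid))
    m <- nrow(reps)
    reps$ct <- reps$base_ct + rnorm(m, 0, noise$replicate_sd)
    aber <- runif(m) < noise$aberrant_rate
    if (any(aber))
      reps$ct[aber] <- reps$ct[aber] +
        sample(c(-1, 1), sum(aber), replace = TRUE) * noise$aberrant_shift
    reps$is_aberrant <- aber
    reps <- reps[order(reps$sample_id, reps$is_housekeeper, reps$gene,
                       reps$replicate_index), ]
    rownames(reps) <- NULL
    reps[, c("sample_id", "gene", "replicate_index", "ct",
             "is_housekeeper", "is_aberrant")]
  })
}

#' Simulate a complete study: manifest plus raw Ct plate
#'
#' Convenience wrapper chaining [generate_cohort()],
#' [generate_expression()] and [generate_ct_table()] under one seed, so a
#' full synthetic study is reproducible from a single integer.
#'
#' @param cohort a [cohort_spec()].
#' @param genes a [gene_spec()] or list of them.
#' @param noise a [ct_noise_spec()].
#' @param seed integer seed governing all draws.
#' @return A list with \code{manifest}, \code{expression} (ground truth) and
#'   \code{ct_table}.
#' @export
simulate_study <- function(cohort = cohort_spec(),
                           genes = gene_spec("TNFSF13"),
                           noise = ct_noise_spec(),
                           seed = NULL) {
  with_seed(seed, {
    manifest <- generate_cohort(cohort)
    expression <- generate_expression(manifest, genes)
    ct <- generate_ct_table(expression, noise)
    list(manifest = manifest, expression = expression, ct_table = ct)
  })
}
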