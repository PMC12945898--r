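#' Specification of a synthetic cohort
#'
#' Describes a generative population for end-to-end pipeline testing:
#' subjects carry latent traits (EEA, SEA, threshold gap B, nondecision time
#' t0, and go-failure probability on the logit scale) drawn from a
#' multivariate normal, which map to accuracy-coded LBA rates by the exact
#' inverse of the EEA/SEA definitions,
#' `v_match = SEA + EEA/2`, `v_mismatch = SEA - EEA/2`, plus condition
#' offsets. Criterion scores load on standardized latent EEA only, with
#' family and site random intercepts; subjects are nested in families which
#' are nested in sites.
#'
#' Defaults emulate a 2-back-style design (three trial types, 2 s window,
#' 300 trials per condition) on 40 subjects -- small enough for routine runs;
#' `n_subjects = 200` gives a fuller cohort. Latent means/SDs sit in the
#' range typical of published LBA fits; condition offsets make lures harder
#' and novels easier while summing to zero so latent EEA/SEA equal their
#' condition-averaged counterparts.
#'
#' @param n_subjects Number of subjects.
#' @param task Task design to emulate.
#' @param trials_per_condition Trials per condition per subject.
#' @param latent_mean,latent_sd Named vectors over
#'   `EEA, SEA, B, t0, p_gf_logit`.
#' @param latent_cor Correlation matrix for the latent traits (default
#'   identity: EEA and SEA vary independently).
#' @param A Start-point range (constant across subjects).
#' @param sv_mismatch Mismatching-rate SD (constant across subjects).
#' @param offsets_match,offsets_mismatch Named per-condition rate offsets.
#' @param criterion_loadings Named vector of loadings of each criterion on
#'   standardized latent EEA (`0.45` gives about 20% criterion variance).
#' @param family_sd,site_sd,criterion_resid_total SDs of family and site
#'   intercepts; residual SD is set so each criterion has unit total
#'   variance.
#' @param n_families,n_sites Nesting structure.
#' @param window Response window in seconds; `NULL` uses the task's design
#'   window (2 s n-back, 3 s numerosity). Override to study censoring-free
#'   regimes.
#' @param seed Default seed carried by the spec.
#' @return A list of class `population_spec`.
#' @export
population_spec <- function(n_subjects = 40,
                            task = "nback2",
                            trials_per_condition = 300,
                            latent_mean = c(EEA = 1.5, SEA = 2, B = 1,
                                            t0 = 0.3, p_gf_logit = qlogis(0.02)),
                            latent_sd = c(EEA = 0.7, SEA = 0.6, B = 0.25,
                                          t0 = 0.05, p_gf_logit = 0.5),
                            latent_cor = diag(5),
                            A = 0.5,
                            sv_mismatch = 1,
                            offsets_match = NULL,
                            offsets_mismatch = NULL,
                            criterion_loadings = c(criterion = 0.45),
                            family_sd = 0.3,
                            site_sd = 0.1,
                            criterion_resid_total = 1,
                            n_families = NULL,
                            n_sites = 4,
                            window = NULL,
                            seed = 1) {
  design <- task_design(task)
  nc <- length(design$conditions)
  if (is.null(offsets_match)) {
    offsets_match <- if (design$task %in% c("nback", "nback0", "nback2")) {
      c(target = 0, lure = -0.35, novel = 0.35)
    } else {
      c(many_easy = 0.3, few_easy = 0.3, many_hard = -0.3, few_hard = -0.3)
    }
  }
  if (is.null(offsets_mismatch)) {
    offsets_mismatch <- -offsets_match
  }
  if (is.null(n_families)) n_families <- max(2, ceiling(n_subjects / 2))
  stopifnot(trials_per_condition >= 1, all(latent_sd >= 0))
  ev <- eigen(latent_cor, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 1e-10)) {
    abort("latent correlation matrix must be positive definite",
          class = "ea_spec_error")
  }
  structure(
    list(n_subjects = n_subjects, task = design$task,
         trials_per_condition = trials_per_condition,
         latent_mean = latent_mean, latent_sd = latent_sd,
         latent_cor = latent_cor, A = A, sv_mismatch = sv_mismatch,
         offsets_match = offsets_match[design$conditions],
         offsets_mismatch = offsets_mismatch[design$conditions],
         criterion_loadings = criterion_loadings,
         window = window,
         family_sd = family_sd, site_sd = site_sd,
         criterion_resid_total = criterion_resid_total,
         n_families = n_families, n_sites = n_sites, seed = seed),
    class = "population_spec"
  )
}

#' Generate a synthetic population
#'
#' Draws per-subject latent traits from the spec's multivariate normal
#' (redrawing subjects whose B, t0 or implied parameters fall outside valid
#' ranges), maps them to per-condition LBA rates, and assigns subjects to
#' families nested in sites.
#'
#' @param spec A [population_spec()].
#' @param seed Integer seed; defaults to `spec$seed`.
#' @return A tibble with one row per subject: nesting labels, latent traits
#'   (`EEA_true`, `SEA_true`, ...), and a `params` list-column of
#'   `lba_params`.
#' @export
generate_population <- function(spec, seed = spec$seed) {
  set.seed(seed)
  nms <- names(spec$latent_mean)
  Sigma <- diag(spec$latent_sd) %*% spec$latent_cor %*% diag(spec$latent_sd)
  draw_valid <- function(n) {
    out <- matrix(NA_real_, 0, length(nms), dimnames = list(NULL, nms))
    while (nrow(out) < n) {
      cand <- MASS::mvrnorm(n, mu = spec$latent_mean, Sigma = Sigma)
      cand <- matrix(cand, ncol = length(nms), dimnames = list(NULL, nms))
      ok <- cand[, "B"] > 0.05 & cand[, "t0"] > 0.06 & cand[, "t0"] < 0.95
      out <- rbind(out, cand[ok, , drop = FALSE])
    }
    out[seq_len(n), , drop = FALSE]
  }
  lat <- draw_valid(spec$n_subjects)
  design <- task_design(spec$task)
  families <- rep(seq_len(spec$n_families), length.out = spec$n_subjects)
  family_site <- rep(seq_len(spec$n_sites), length.out = spec$n_families)
  pop <- tibble(
    subject = sprintf("s%03d", seq_len(spec$n_subjects)),
    family = sprintf("f%03d", sort(families)),
    EEA_true = unname(lat[, "EEA"]), SEA_true = unname(lat[, "SEA"]),
    B_true = unname(lat[, "B"]), t0_true = unname(lat[, "t0"]),
    p_gf_true = unname(plogis(lat[, "p_gf_logit"]))
  )
  pop$site <- sprintf("site%d", family_site[as.integer(sub("f", "", pop$family))])
  pop$params <- purrr::pmap(
    list(pop$EEA_true, pop$SEA_true, pop$B_true, pop$t0_true, pop$p_gf_true),
    function(eea, sea, B, t0, p_gf) {
      lba_params(
        spec$task,
        v_match = sea + eea / 2 + spec$offsets_match,
        v_mismatch = sea - eea / 2 + spec$offsets_mismatch,
        B = B, A = spec$A, sv_mismatch = spec$sv_mismatch,
        t0 = t0, p_gf = p_gf
      )
    }
  )
  attr(pop, "spec") <- spec
  pop
}

#' Generate trial data for a synthetic population
#'
#' Simulates every subject's trials from their true LBA parameters (exact
#' simulator, including go failures and window censoring), with per-subject
#' seeds derived deterministically from the master seed.
#'
#' @param population Output of [generate_population()].
#' @param spec The [population_spec()] (defaults to the one attached to the
#'   population).
#' @param seed Master seed; defaults to `spec$seed + 1`.
#' @return A trial tibble covering all subjects, with `family` and `site`
#'   columns joined on.
#' @export
generate_trials <- function(population, spec = attr(population, "spec"),
                            seed = spec$seed + 1) {
  design <- task_design(spec$task)
  counts <- setNames(rep(spec$trials_per_condition, length(design$conditions)),
                     design$conditions)
  set.seed(seed)
  subject_seeds <- sample.int(.Machine$integer.max - 1L, nrow(population))
  trials <- purrr::map2(
    population$params, seq_len(nrow(population)),
    function(p, i) {
      lba_simulate(p, counts, window = spec$window, seed = subject_seeds[i],
                   subject = population$subject[i])
    }
  ) |> dplyr::bind_rows()
  dplyr::left_join(trials,
                   dplyr::select(population, subject, family, site),
                   by = "subject")
}

#' Generate criterion scores for a synthetic population
#'
#' Each criterion is `lambda * standardized latent EEA + family intercept +
#' site intercept + normal noise`, scaled to unit total variance, so a
#' loading of `lambda` yields a true criterion R-squared of `lambda^2`.
#' SEA does not enter: criteria load on efficiency only.
#'
#' @inheritParams generate_trials
#' @param seed Seed; defaults to `spec$seed + 2`.
#' @return A tibble: `subject`, `family`, `site`, one column per criterion.
#' @export
generate_criteria <- function(population, spec = attr(population, "spec"),
                              seed = spec$seed + 2) {
  set.seed(seed)
  n <- nrow(population)
  z_eea <- as.vector(scale(population$EEA_true))
  fam_levels <- unique(population$family)
  site_levels <- unique(population$site)
  out <- dplyr::select(population, subject, family, site)
  for (k in seq_along(spec$criterion_loadings)) {
    lam <- spec$criterion_loadings[[k]]
    resid_var <- spec$criterion_resid_total^2 - lam^2 -
      spec$family_sd^2 - spec$site_sd^2
    if (resid_var <= 0) {
      abort("criterion loading and intercept SDs exceed total variance",
            class = "ea_spec_error")
    }
    fam_int <- setNames(rnorm(length(fam_levels), 0, spec$family_sd), fam_levels)
    site_int <- setNames(rnorm(length(site_levels), 0, spec$site_sd), site_levels)
    out[[names(spec$criterion_loadings)[k]]] <-
      lam * z_eea + fam_int[population$family] + site_int[population$site] +
      rnorm(n, 0, sqrt(resid_var))
  }
  out
}

#' Generate a complete synthetic study
#'
#' Population, trials and criterion scores in one call.
#'
#' @param spec A [population_spec()].
#' @param seed Master seed; defaults to `spec$seed`.
#' @return A list with `population`, `trials`, `criteria` and the `spec`.
#' @export
#' @examples
#' study <- simulate_study(population_spec(n_subjects = 4,
#'                                         trials_per_condition = 20))
#' dplyr::count(study$trials, subject)
simulate_study <- function(spec = population_spec(), seed = spec$seed) {
  population <- generate_population(spec, seed = seed)
  trials <- generate_trials(population, spec, seed = seed + 1)
  criteria <- generate_criteria(population, spec, seed = seed + 2)
  list(population = population, trials = trials, criteria = criteria,
       spec = spec)
}
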