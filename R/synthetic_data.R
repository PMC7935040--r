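#' Synthetic cohort configuration
#'
#' The generator emulates the *derived* tables a structural-connectome
#' study produces — streamline-count matrices, regional gray-matter
#' volumes, total intracranial volume — not raw imaging. Defaults mirror
#' the reference study's dimensions: 65 subjects, 120 atlas regions.
#'
#' @param n_subjects number of subjects (default 65).
#' @param n_regions number of atlas regions (default 120).
#' @param template_degree_exponent Pareto tail exponent of the group
#'   template's strength distribution (default 2.5; smaller = heavier
#'   tail, more hub-dominated).
#' @param subject_noise_sd SD of the multiplicative lognormal edge noise
#'   giving each subject their own connectome (default 0.3).
#' @param rgm_topology_coupling target (Spearman) correlation, in
#'   `[-1, 1]`, between regional gray matter and *template* node strength
#'   (default 0.5). The same dial weights the subject-level coupling of the
#'   gray-matter jitter to each subject's own topology; degree-preserving
#'   rewiring destroys exactly the signal it encodes.
#' @param tiv_mean,tiv_sd total-intracranial-volume distribution, mm^3
#'   (defaults 1.5e6 and 1.2e5, adult-range values).
#' @param rgm_mean,rgm_sd regional gray-matter scale, mm^3 (defaults 8000
#'   and 1500).
#' @param seed master seed; all randomness flows from it through named
#'   substreams (template, subjects, volumetrics).
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 65, n_regions = 120,
                          template_degree_exponent = 2.5,
                          subject_noise_sd = 0.3,
                          rgm_topology_coupling = 0.5,
                          tiv_mean = 1.5e6, tiv_sd = 1.2e5,
                          rgm_mean = 8000, rgm_sd = 1500,
                          seed = 1L) {
  if (n_subjects < 1 || n_regions < 4)
    stop_ctrl("need n_subjects >= 1 and n_regions >= 4")
  if (abs(rgm_topology_coupling) > 1)
    stop_ctrl("rgm_topology_coupling must lie in [-1, 1]")
  if (subject_noise_sd < 0 || tiv_sd <= 0 || rgm_sd <= 0)
    stop_ctrl("all SDs must be positive")
  if (template_degree_exponent <= 1)
    stop_ctrl("template_degree_exponent must exceed 1")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_regions = as.integer(n_regions),
                 template_degree_exponent = template_degree_exponent,
                 subject_noise_sd = subject_noise_sd,
                 rgm_topology_coupling = rgm_topology_coupling,
                 tiv_mean = tiv_mean, tiv_sd = tiv_sd,
                 rgm_mean = rgm_mean, rgm_sd = rgm_sd,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Group connectome template: weighted-configuration construction whose
# expected strengths follow a truncated Pareto with the configured
# exponent, with lognormal edge jitter, scaled to streamline-count
# magnitudes.
build_template <- function(cfg) {
  n <- cfg$n_regions
  with_seed(seed_stream(cfg$seed, "template"), {
    u <- stats::runif(n)
    s <- (1 - u)^(-1 / (cfg$template_degree_exponent - 1))
    # cap extreme hubs: uncapped Pareto draws occasionally produce a node
    # so strong that the thresholded graph degenerates into a star (a
    # region adjacent to everything), which real thresholded connectomes
    # do not show and which leaves no legal degree-preserving swaps
    s <- pmin(s, 6)
    W <- outer(s, s) / sum(s)
    # edge-level dispersion ~ 1 log-unit: streamline counts between fixed
    # region pairs span orders of magnitude, and this spread keeps the
    # top-decile edges from collapsing onto a frozen hub clique
    jitter <- matrix(stats::rnorm(n * n, sd = 1.0), n, n)
    jitter <- (jitter + t(jitter)) / 2
    W <- W * exp(jitter) * 500
    diag(W) <- 0
    (W + t(W)) / 2
  })
}

#' Generate a synthetic cohort
#'
#' Builds one group template with heavy-tailed node strengths, derives each
#' subject's connectome by multiplicative lognormal edge noise, and draws
#' volumetrics coupled to topology by `rgm_topology_coupling` through two
#' channels governed by the same dial:
#'
#' 1. *Between regions*: the mean gray-matter profile is a Gaussian mixture
#'    of the rank-Gaussianized template strength and an orthogonalized
#'    noise vector, so its Spearman correlation with template strength is
#'    realized within about 0.05 of the target on every seed.
#' 2. *Within regions, between subjects*: the small per-subject jitter is
#'    coupled (with the same weight) to the within-region deviation of the
#'    subject's own nodal average controllability orthogonalized to both
#'    their nodal *strength* deviation and their *binary degree* deviation,
#'    all computed on the default pipeline (10% proportional threshold,
#'    singular-value normalization). Gray matter thus carries
#'    controllability information beyond what degree carries — the
#'    quantity the mixed models estimate as the gray-matter coefficient —
#'    and because strength and binary degree are exactly what
#'    degree-preserving rewiring conserves, the encoded signal is
#'    placement-specific and rewiring destroys it.
#'
#' @param cfg a [cohort_config()].
#' @return List with `connectomes` (named list of
#'   [connectivity_matrix()]), `volumetrics` (named list of
#'   [subject_volumetrics()]), `atlas`, `template` (numeric matrix), `cfg`.
#' @export
generate_cohort <- function(cfg) {
  if (!inherits(cfg, "cohort_config")) stop_ctrl("expected a cohort_config")
  n <- cfg$n_regions
  atlas <- if (n == 120L) default_atlas()
           else region_atlas(sprintf("region_%03d", seq_len(n)))
  template <- build_template(cfg)
  subj_ids <- sprintf("sub-%03d", seq_len(cfg$n_subjects))

  connectomes <- lapply(seq_len(cfg$n_subjects), function(i) {
    with_seed(seed_stream(cfg$seed, "subjects", i), {
      noise <- matrix(stats::rnorm(n * n, sd = cfg$subject_noise_sd), n, n)
      noise <- (noise + t(noise)) / 2
      w <- template * exp(noise)
      diag(w) <- 0
      connectivity_matrix(w, atlas = atlas, subject_id = subj_ids[i])
    })
  })
  names(connectomes) <- subj_ids

  s <- rowSums(template)
  # rank-Gaussianized template strength: mixing on the Gaussian scale makes
  # the realized Spearman correlation track the coupling for any tail
  rg <- stats::qnorm((rank(s) - 0.5) / n)
  s_hat <- as.vector(scale(rg))
  cpl <- cfg$rgm_topology_coupling
  # per-subject nodal AC and strength under pipeline defaults; the rGM
  # jitter couples to the within-region AC deviation orthogonal to the
  # strength deviation (controllability information beyond degree)
  met <- lapply(connectomes, function(C) {
    thr <- threshold_proportional(C$weights, 0.10)
    list(ac = average_controllability(
           normalize_adjacency(thr, "singular_value")),
         st = rowSums(thr),
         deg = rowSums(thr > 0))
  })
  q_ac <- vapply(met, `[[`, numeric(n), "ac")
  q_st <- vapply(met, `[[`, numeric(n), "st")
  q_deg <- vapply(met, `[[`, numeric(n), "deg")
  dev <- if (cfg$n_subjects >= 4L) {
    std_rows <- function(m) {
      d <- (m - rowMeans(m)) / apply(m, 1, stats::sd)
      d[!is.finite(d)] <- 0
      d
    }
    proj_out <- function(y, x) {
      y - x * rowSums(y * x) / pmax(rowSums(x^2), 1e-12)
    }
    d_st <- std_rows(q_st)
    d_deg <- proj_out(std_rows(q_deg), d_st)  # degree beyond strength
    perp <- proj_out(proj_out(std_rows(q_ac), d_st), d_deg)
    std_rows(perp)
  } else matrix(0, n, cfg$n_subjects)
  jitter_sd <- 0.1
  volumetrics <- with_seed(seed_stream(cfg$seed, "volumetrics"), {
    z <- stats::rnorm(n)
    z_perp <- stats::residuals(stats::lm(z ~ s_hat))
    z_perp <- as.vector(scale(z_perp))
    mix0 <- cpl * s_hat + sqrt(max(0, 1 - cpl^2)) * z_perp
    out <- lapply(seq_len(cfg$n_subjects), function(i) {
      jit <- cpl * dev[, i] + sqrt(max(0, 1 - cpl^2)) * stats::rnorm(n)
      mix <- mix0 + jitter_sd * jit
      rgm <- pmax(cfg$rgm_mean + cfg$rgm_sd * mix, cfg$rgm_mean / 16)
      tiv <- abs(stats::rnorm(1, cfg$tiv_mean, cfg$tiv_sd))
      if (sum(rgm) > tiv) rgm <- rgm * 0.9 * tiv / sum(rgm)
      subject_volumetrics(subj_ids[i], tiv, rgm, atlas)
    })
    names(out) <- subj_ids
    out
  })

  list(connectomes = connectomes, volumetrics = volumetrics,
       atlas = atlas, template = template, cfg = cfg)
}

#' Configuration for a mixed-model recovery fixture
#'
#' @param true_betas named numeric vector over the canonical terms
#'   `degree`, `rgm`, `degree:rgm`, `tiv` (omitted terms are zero).
#' @param random_intercept_sd SD of the per-subject intercept (default
#'   0.5).
#' @param residual_sd residual SD (default 1).
#' @param n_subjects,n_regions fixture dimensions (defaults 65 and 120).
#' @param response `"ac"` or `"mc"` — which outcome column carries the
#'   signal.
#' @param seed integer seed.
#' @return Object of class `lme_fixture_config`.
#' @export
lme_fixture_config <- function(true_betas = c(degree = 0.36, rgm = 0.44,
                                              `degree:rgm` = 0.04),
                               random_intercept_sd = 0.5,
                               residual_sd = 1,
                               n_subjects = 65, n_regions = 120,
                               response = c("ac", "mc"),
                               seed = 1L) {
  response <- match.arg(response)
  allowed <- c("degree", "rgm", "degree:rgm", "tiv")
  bad <- setdiff(names(true_betas), allowed)
  if (length(bad) > 0)
    stop_ctrl("unknown term(s) in true_betas: ",
              paste(bad, collapse = ", "),
              " (allowed: ", paste(allowed, collapse = ", "), ")")
  if (!is.numeric(residual_sd) || residual_sd < 0)
    stop_ctrl("residual_sd must be non-negative")
  if (random_intercept_sd < 0)
    stop_ctrl("random_intercept_sd must be non-negative")
  structure(list(true_betas = true_betas,
                 random_intercept_sd = random_intercept_sd,
                 residual_sd = residual_sd,
                 n_subjects = as.integer(n_subjects),
                 n_regions = as.integer(n_regions),
                 response = response,
                 seed = as.integer(seed)),
            class = "lme_fixture_config")
}

#' Generate a study table with known mixed-model ground truth
#'
#' Predictors are simulated already standardized (N(0,1) per row for degree
#' and rGM, per subject for TIV) and the response is built exactly as
#' `X beta + subject intercept + residual noise`, so the true coefficients
#' are recoverable by [fit_lme()]. The returned table's scaled view equals
#' its raw view.
#'
#' @param cfg an [lme_fixture_config()].
#' @return A `study_table` ready for [fit_lme()] (scaled view populated).
#' @export
generate_lme_fixture <- function(cfg) {
  if (!inherits(cfg, "lme_fixture_config"))
    stop_ctrl("expected an lme_fixture_config")
  ns <- cfg$n_subjects
  nr <- cfg$n_regions
  subj <- sprintf("sub-%03d", seq_len(ns))
  regs <- sprintf("region_%03d", seq_len(nr))
  bt <- cfg$true_betas
  getb <- function(term) if (term %in% names(bt)) unname(bt[term]) else 0
  with_seed(cfg$seed, {
    d <- expand.grid(region_name = regs, subject_id = subj,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    d <- d[, c("subject_id", "region_name")]
    nrow_d <- nrow(d)
    d$strength_z <- stats::rnorm(nrow_d)
    d$rgm_z <- stats::rnorm(nrow_d)
    tiv_s <- stats::rnorm(ns)
    d$tiv_z <- tiv_s[match(d$subject_id, subj)]
    b_s <- stats::rnorm(ns, sd = cfg$random_intercept_sd)
    y <- getb("degree") * d$strength_z +
      getb("rgm") * d$rgm_z +
      getb("degree:rgm") * d$strength_z * d$rgm_z +
      getb("tiv") * d$tiv_z +
      b_s[match(d$subject_id, subj)] +
      stats::rnorm(nrow_d, sd = cfg$residual_sd)
    other <- stats::rnorm(nrow_d)
    if (cfg$response == "ac") {
      d$ac_z <- y; d$mc_z <- other
    } else {
      d$mc_z <- y; d$ac_z <- other
    }
    d$ac <- d$ac_z; d$mc <- d$mc_z
    d$strength <- d$strength_z; d$rgm <- d$rgm_z; d$tiv <- d$tiv_z
    d <- d[order(d$subject_id, d$region_name), , drop = FALSE]
    rownames(d) <- NULL
    attr(d, "scaling") <- list(pre_standardized = TRUE)
    class(d) <- c("study_table", "data.frame")
    d
  })
}
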