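# Canonical variable grammar shared by model specs and coefficient lookup.
# The study's models are written over ac, mc, degree (weighted strength),
# rgm, tiv and region; internally these map to the scaled columns of the
# study table.
CANONICAL_MAP <- c(ac = "ac_z", mc = "mc_z",
                   degree = "strength_z", strength = "strength_z",
                   rgm = "rgm_z", tiv = "tiv_z",
                   region = "region", regions = "region")

canonical_to_column <- function(x) {
  x <- trimws(x)
  out <- unname(CANONICAL_MAP[x])
  if (anyNA(out))
    stop_ctrl("unknown variable(s): ",
              paste(x[is.na(out)], collapse = ", "),
              " (known: ", paste(names(CANONICAL_MAP), collapse = ", "), ")")
  out
}

# One fixed-effect term in the restricted grammar: a variable name, a
# crossing "a x b" (unicode times, 'x' or '*'; expands to a + b + a:b), or a
# bare interaction "a:b".
parse_term <- function(term) {
  term <- trimws(term)
  term <- gsub("×", "*", term)
  term <- gsub("(?<=[a-z_]) x (?=[a-z_])", "*", term, perl = TRUE)
  if (grepl("\\*", term)) {
    parts <- canonical_to_column(strsplit(term, "\\*")[[1]])
    paste(parts, collapse = " * ")
  } else if (grepl(":", term, fixed = TRUE)) {
    parts <- canonical_to_column(strsplit(term, ":", fixed = TRUE)[[1]])
    paste(parts, collapse = ":")
  } else {
    canonical_to_column(term)
  }
}

#' Mixed-model specification
#'
#' Describes one linear mixed-effects model in the restricted grammar
#' `response ~ term (+ term)*` with `x`-crossings and the fixed random part
#' `(1 | participants)` — exactly one random intercept by participant, fixed
#' slopes. Variables are the canonical names `ac`, `mc`, `degree` (the
#' weighted nodal strength), `rgm`, `tiv`, `region`.
#'
#' @param response `"ac"` or `"mc"`.
#' @param fixed_terms character vector of term descriptors, e.g.
#'   `c("tiv", "region", "degree x rgm")`.
#' @param label text label carried into results.
#' @return Object of class `model_spec`.
#' @seealso [model_spec_one()], [model_spec_two()] for the two canonical
#'   study models.
#' @export
model_spec <- function(response = c("ac", "mc"), fixed_terms,
                       label = NULL) {
  response <- match.arg(response)
  if (length(fixed_terms) < 1L) stop_ctrl("fixed_terms must be non-empty")
  rhs_terms <- vapply(fixed_terms, parse_term, character(1))
  rhs <- paste(rhs_terms, collapse = " + ")
  structure(list(response = response,
                 fixed_terms = as.character(fixed_terms),
                 rhs = rhs,
                 label = label %||% paste0(response, " ~ ",
                                           paste(fixed_terms,
                                                 collapse = " + "))),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", x$label, " + (1|participants)\n", sep = "")
  invisible(x)
}

#' Canonical model 1: whole-brain degree-by-gray-matter interaction
#'
#' `controllability ~ TIV + Regions + Nodal degree x rGM +
#' (1|participants)`: quantifies the contribution of regional gray matter
#' and nodal degree (and their interaction) after controlling for regional
#' differences in the outcome.
#'
#' @param response `"ac"` or `"mc"`.
#' @return A [model_spec()].
#' @export
model_spec_one <- function(response = c("ac", "mc")) {
  response <- match.arg(response)
  model_spec(response, c("tiv", "region", "degree x rgm"),
             label = paste0("model1: ", response,
                            " ~ tiv + region + degree x rgm"))
}

#' Canonical model 2: regional interaction model
#'
#' `controllability ~ TIV + Regions x Nodal degree + Regions x rGM +
#' (1|participants)`: lets the degree and gray-matter slopes vary by
#' region, from which per-region effects are extracted with
#' [regional_effects()].
#'
#' @param response `"ac"` or `"mc"`.
#' @return A [model_spec()].
#' @export
model_spec_two <- function(response = c("ac", "mc")) {
  response <- match.arg(response)
  model_spec(response, c("tiv", "region x degree", "region x rgm"),
             label = paste0("model2: ", response,
                            " ~ tiv + region x degree + region x rgm"))
}

model_frame <- function(tab, spec) {
  if (!inherits(tab, "study_table")) stop_ctrl("expected a study_table")
  if (!has_scaled_view(tab))
    stop_ctrl("study table has no scaled view; run center_and_scale() first")
  d <- as.data.frame(tab)
  d$subject <- factor(d$subject_id)
  # treatment contrasts, alphabetically first region as reference
  d$region <- factor(d$region_name, levels = sort(unique(d$region_name)))
  d
}

#' Fit a linear mixed-effects model
#'
#' Fits `spec` on the scaled study table with a participant random
#' intercept via [lme4::lmer()]. Inference on fixed effects is asymptotic
#' Wald: `z = beta / se`, two-sided normal p-values and symmetric 95%
#' confidence intervals. `method = "ML"` must be used for any fit entering
#' a likelihood-ratio comparison; the final reported model is conventionally
#' refit with `"REML"`.
#'
#' The fixed-effects design is rank-checked before fitting; aliased columns
#' are named in the error. Optimizer non-convergence does not raise: the
#' result carries `converged = FALSE` plus the diagnostic messages.
#'
#' @param tab a scaled `study_table`.
#' @param spec a [model_spec()].
#' @param method `"ML"` or `"REML"`.
#' @param conf_level Wald confidence level (default 0.95).
#' @return Object of class `model_result`: coefficient table (`term`,
#'   `beta`, `se`, `ci_low`, `ci_high`, `p_raw`, `p_bonf`), `log_likelihood`,
#'   `n_obs`, `converged`, `fit_method`, `spec`, plus the underlying lme4
#'   fit in `$fit`.
#' @export
fit_lme <- function(tab, spec, method = c("ML", "REML"),
                    conf_level = 0.95) {
  method <- match.arg(method)
  if (!inherits(spec, "model_spec")) stop_ctrl("spec must be a model_spec")
  d <- model_frame(tab, spec)
  if (nlevels(d$subject) < 2L)
    stop_ctrl("mixed model needs >= 2 participants, got ",
              nlevels(d$subject))
  fixed <- stats::as.formula(
    paste(canonical_to_column(spec$response), "~", spec$rhs))
  X <- stats::model.matrix(fixed, d)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop_ctrl("fixed-effects design is rank deficient; aliased term(s): ",
              paste(aliased, collapse = ", "))
  }
  full <- stats::as.formula(
    paste(canonical_to_column(spec$response), "~", spec$rhs,
          "+ (1 | subject)"))
  diagnostics <- character(0)
  fit <- withCallingHandlers(
    lme4::lmer(full, data = d, REML = (method == "REML"),
               control = lme4::lmerControl(calc.derivs = FALSE)),
    warning = function(w) {
      diagnostics <<- c(diagnostics, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  conv_code <- fit@optinfo$conv$opt
  converged <- is.null(conv_code) || conv_code == 0
  messages <- unlist(fit@optinfo$conv$lme4$messages) %||% character(0)
  if (any(grepl("failed to converge", c(messages, diagnostics))))
    converged <- FALSE
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  coefs <- data.frame(term = names(beta), beta = unname(beta),
                      se = unname(se),
                      ci_low = unname(beta - zq * se),
                      ci_high = unname(beta + zq * se),
                      p_raw = unname(p),
                      p_bonf = unname(p),  # family correction applied by
                                           # regional_effects()
                      stringsAsFactors = FALSE)
  structure(list(coefficients = coefs,
                 log_likelihood = as.numeric(stats::logLik(fit)),
                 n_obs = nrow(d),
                 n_groups = nlevels(d$subject),
                 converged = converged,
                 fit_method = method,
                 conf_level = conf_level,
                 diagnostics = c(diagnostics, messages),
                 spec = spec,
                 fit = fit),
            class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat("<model_result> ", x$spec$label, " [", x$fit_method, "], n = ",
      x$n_obs, " obs / ", x$n_groups, " participants, logLik = ",
      format(x$log_likelihood), if (!x$converged) " (NOT converged)",
      "\n", sep = "")
  show <- x$coefficients[!grepl("^region", x$coefficients$term) |
                           grepl(":", x$coefficients$term, fixed = TRUE), ]
  show <- utils::head(show, 8)
  print(format(show, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Stepwise forward selection by likelihood-ratio test
#'
#' Starting from `base`, candidate terms are added in the given order; each
#' is retained iff the likelihood-ratio test between the ML fits with and
#' without it (chi-squared with df = number of added fixed-effect
#' parameters) has `p < alpha`. REML fits are invalid for comparisons
#' across fixed effects, so all fits here are ML.
#'
#' @param tab a scaled `study_table`.
#' @param base a [model_spec()].
#' @param candidate_terms ordered character vector of term descriptors in
#'   the [model_spec()] grammar.
#' @param alpha retention threshold (default 0.05).
#' @return List with `spec` (the winning [model_spec()]) and `trace`
#'   (data.frame: term, lr_stat, df, p, kept).
#' @export
stepwise_select <- function(tab, base, candidate_terms, alpha = 0.05) {
  if (length(candidate_terms) < 1L)
    stop_ctrl("candidate_terms must be non-empty")
  current <- base
  fit0 <- fit_lme(tab, current, method = "ML")
  trace <- data.frame(term = character(0), lr_stat = numeric(0),
                      df = integer(0), p = numeric(0), kept = logical(0))
  for (term in candidate_terms) {
    cand <- model_spec(current$response,
                       c(current$fixed_terms, term),
                       label = paste0(current$label, " + ", term))
    fit1 <- fit_lme(tab, cand, method = "ML")
    df <- nrow(fit1$coefficients) - nrow(fit0$coefficients)
    if (df <= 0)
      stop_ctrl("candidate '", term, "' adds no parameters; ",
                "non-nested comparisons are unsupported")
    lr <- 2 * (fit1$log_likelihood - fit0$log_likelihood)
    p <- stats::pchisq(max(lr, 0), df = df, lower.tail = FALSE)
    kept <- p < alpha
    trace <- rbind(trace, data.frame(term = term, lr_stat = lr, df = df,
                                     p = p, kept = kept))
    if (kept) {
      current <- cand
      fit0 <- fit1
    }
  }
  list(spec = current, trace = trace)
}

#' Per-region interaction effects with Bonferroni correction
#'
#' Extracts the per-region slope of rGM (or degree) from a fitted model 2.
#' Under treatment contrasts the reference region's slope is the main
#' effect and every other region's slope is main effect + its interaction
#' contrast; standard errors combine the coefficient covariances
#' accordingly. p-values are Bonferroni-corrected over the family size
#' (the number of regions reported simultaneously).
#'
#' @param result a [fit_lme()] result whose model contains `region x rgm`
#'   (and/or `region x degree`) interactions.
#' @param family `"rgm"` or `"degree"`.
#' @param conf_level Wald confidence level.
#' @return data.frame: `region`, `beta`, `se`, `ci_low`, `ci_high`,
#'   `p_raw`, `p_bonf`, sorted by atlas/alphabetical region order.
#' @export
regional_effects <- function(result, family = c("rgm", "degree"),
                             conf_level = 0.95) {
  family <- match.arg(family)
  if (!inherits(result, "model_result"))
    stop_ctrl("result must come from fit_lme()")
  vcol <- canonical_to_column(family)
  beta <- lme4::fixef(result$fit)
  V <- as.matrix(stats::vcov(result$fit))
  nm <- names(beta)
  pat <- paste0("^region(.+):", vcol, "$|^", vcol, ":region(.+)$")
  int_idx <- grep(pat, nm)
  if (!(vcol %in% nm) || length(int_idx) == 0L)
    stop_ctrl("model has no region x ", family,
              " interaction terms; fit model 2 first")
  int_regions <- sub(paste0(":", vcol, "$"), "",
                     sub(paste0("^", vcol, ":"), "", nm[int_idx]))
  int_regions <- sub("^region", "", int_regions)
  d <- stats::model.frame(result$fit)
  regions <- levels(d$region)
  m <- length(regions)
  main_idx <- which(nm == vcol)
  est <- se <- numeric(m)
  for (i in seq_len(m)) {
    L <- numeric(length(beta))
    L[main_idx] <- 1
    j <- int_idx[match(regions[i], int_regions)]
    if (!is.na(j)) L[j] <- 1
    est[i] <- sum(L * beta)
    se[i] <- sqrt(drop(t(L) %*% V %*% L))
  }
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  p_raw <- 2 * stats::pnorm(-abs(est / se))
  data.frame(region = regions, beta = est, se = se,
             ci_low = est - zq * se, ci_high = est + zq * se,
             p_raw = p_raw,
             p_bonf = pmin(1, p_raw * m),
             stringsAsFactors = FALSE)
}

#' Serialize a model result to JSON and TSV
#'
#' @param result a `model_result`.
#' @param path_json JSON summary path; `NULL` to skip.
#' @param path_tsv coefficient table path; `NULL` to skip.
#' @export
write_model_result <- function(result, path_json = NULL, path_tsv = NULL) {
  if (!is.null(path_tsv))
    utils::write.table(result$coefficients, path_tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(
      list(label = result$spec$label,
           fit_method = result$fit_method,
           log_likelihood = result$log_likelihood,
           n_obs = result$n_obs,
           n_groups = result$n_groups,
           converged = result$converged,
           coefficients = result$coefficients),
      path_json, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(NULL)
}
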