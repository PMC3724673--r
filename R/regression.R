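# Linear, additive and mixed-effects models of the composition statistics:
# %AT on the 64 codon frequencies; AAUB phylum ANOVA; AAUB ~ s(CUB) as a
# GAM and as a GAMM with nested phylum/genus/species random intercepts and
# %AT random slopes; the KL model (KL ~ s(%AT) + AAUB + random structure);
# KL against genome size; and ML-based AIC comparison.
#
# Mixed models are fitted with mgcv::gamm, which estimates the smooths and
# the nested random effects jointly through nlme::lme: each taxonomy level
# contributes an independent (diagonal) random intercept and random slope
# on the slope covariate. AIC comparisons are between ML refits of the
# underlying lme models.

# model: lm, gam, or a mgcv::gamm-style list(gam=, lme=)
new_cb_fit <- function(model, kind, method, response, data, extra = list()) {
  is_gamm <- is.list(model) && !is.null(model$lme) && !inherits(model, "lm")
  gam_part <- if (is_gamm) model$gam else model
  sm <- if (!is.null(gam_part)) smooth_estimates_grid(gam_part, data) else NULL
  rv <- if (is_gamm) lme_variance_components(model$lme) else NULL
  conv <- if (is_gamm) TRUE else isTRUE(gam_part$converged) ||
    (inherits(gam_part, "lm") && !inherits(gam_part, "gam"))
  fit <- structure(c(list(
    model = gam_part %||% model$lme,
    lme = if (is_gamm) model$lme else NULL,
    kind = kind,
    method = method,
    response = response,
    data = data,
    smooth_estimates = sm,
    random_variances = rv,
    aic = AIC(if (is_gamm) model$lme else model),
    converged = conv
  ), extra), class = "cb_fit")
  fit$r_squared <- fit_r_squared(fit$model, data, response)
  fit
}

fit_r_squared <- function(model, data = NULL, response = NULL) {
  if (inherits(model, "gam")) {
    s <- summary(model)
    unname(s$dev.expl)
  } else if (inherits(model, "lme")) {
    y <- data[[response]]
    1 - sum(resid(model)^2) / sum((y - mean(y))^2)
  } else {
    summary(model)$r.squared
  }
}

# Per-level intercept/slope standard deviations from a nested lme fit,
# excluding the internal blocks gamm uses to represent the smooths.
lme_variance_components <- function(lme) {
  re <- lme$modelStruct$reStruct
  sigma <- lme$sigma
  rows <- list()
  for (nm in rev(names(re))) {         # reStruct stores innermost first
    if (!startsWith(nm, ".grp_")) next # skip gamm's internal smooth blocks
    eff <- colnames(as.matrix(re[[nm]]))
    sds <- sigma * exp(as.numeric(coef(re[[nm]], unconstrained = TRUE)))
    rows[[nm]] <- tibble(
      term = paste0(sub("^\\.grp_", "", nm), ":", eff),
      std_dev = sds[seq_along(eff)]
    )
  }
  rows$residual <- tibble(term = "residual", std_dev = sigma)
  out <- bind_rows(rows)
  out$variance <- out$std_dev^2
  out
}

# Evaluate each univariate smooth term on a 100-point grid with a 2-SE band.
smooth_estimates_grid <- function(model, data) {
  if (!inherits(model, "gam") || length(model$smooth) == 0L) return(NULL)
  rows <- list()
  for (sm in model$smooth) {
    if (inherits(sm, "random.effect")) next
    v <- sm$term
    if (length(v) != 1L || !is.numeric(data[[v]])) next
    grid <- seq(min(data[[v]]), max(data[[v]]), length.out = 100)
    nd <- data[rep(1L, 100), , drop = FALSE]
    nd[[v]] <- grid
    pr <- predict(model, newdata = nd, type = "terms", se.fit = TRUE,
                  newdata.guaranteed = TRUE)
    lab <- sm$label
    fitv <- pr$fit[, lab]
    sev <- pr$se.fit[, lab]
    rows[[lab]] <- tibble(term = lab, x = grid, fit = fitv,
                          lower = fitv - 2 * sev, upper = fitv + 2 * sev)
  }
  if (length(rows)) dplyr::bind_rows(rows) else NULL
}

#' Linear model of genomic %AT on the 64 codon frequencies
#'
#' Ordinary least squares of per-genome %AT on all 64 codon-frequency
#' columns. Codon frequencies are compositional (they sum to 1, and %AT is
#' itself a linear functional of them), so exact collinearity is expected;
#' aliased coefficients are reported as such and the fit is still returned.
#'
#' @param profiles Profile tibble from [profile_cohort()] (needs
#'   `at_fraction` and the `codon_*` columns).
#' @return A `cb_fit` with extra elements `aliased` (names of
#'   non-estimable codon terms) and `coefficients` tibble.
#' @export
fit_at_on_codons <- function(profiles) {
  codon_cols <- paste0("codon_", cb_codons)
  stopifnot(all(codon_cols %in% names(profiles)))
  df <- as.data.frame(profiles[, c("at_fraction", codon_cols)])
  model <- lm(at_fraction ~ ., data = df)
  if (model$df.residual <= 0L) {
    abort("degenerate model: no residual degrees of freedom (n <= rank)")
  }
  cf <- coef(model)
  aliased <- names(cf)[is.na(cf)]
  # %AT is itself a linear functional of the codon frequencies, so lm's
  # "essentially perfect fit" warning is the expected outcome, not a defect
  suppressWarnings({
    s <- summary(model)
    coefs <- as_tibble(s$coefficients, rownames = "term")
    names(coefs) <- c("term", "estimate", "std_error", "statistic", "p_value")
    fit <- new_cb_fit(model, kind = "at_on_codons", method = "OLS",
                      response = "at_fraction", data = profiles,
                      extra = list(aliased = aliased, coefficients = coefs))
  })
  fit
}

#' Phylum ANOVA of amino acid usage bias
#'
#' Dummy-coded OLS of AAUB on phylum, with ranked per-phylum means. The
#' ranking used for "highest/lowest AAUB" queries is restricted to phyla
#' with more than `min_genomes` genomes, since means of tiny phyla are
#' unstable.
#'
#' @param profiles Profile tibble with `genome_id` and `aaub`.
#' @param taxonomy Taxonomy tibble with `genome_id` and `phylum`.
#' @param min_genomes Minimum phylum size for the ranked subset
#'   (default 20).
#' @return A `cb_fit` with extra elements `phylum_means` (all phyla) and
#'   `ranked` (phyla above the size threshold, ordered by mean AAUB).
#' @export
fit_anova_aaub_phylum <- function(profiles, taxonomy, min_genomes = 20) {
  df <- left_join(profiles[, c("genome_id", "aaub")],
                  taxonomy[, c("genome_id", "phylum")], by = "genome_id")
  if (any(is.na(df$phylum))) {
    abort(paste0("genomes missing from taxonomy: ",
                 paste(head(df$genome_id[is.na(df$phylum)], 5), collapse = ", ")))
  }
  df$phylum <- factor(df$phylum)
  if (nlevels(df$phylum) < 2L) abort("degenerate model: a single phylum")
  model <- lm(aaub ~ phylum, data = df)
  means <- df |>
    group_by(.data$phylum) |>
    summarise(n = n(), mean_aaub = mean(.data$aaub), .groups = "drop") |>
    arrange(dplyr::desc(.data$mean_aaub))
  ranked <- means[means$n > min_genomes, ]
  new_cb_fit(model, kind = "anova_aaub_phylum", method = "OLS",
             response = "aaub", data = df,
             extra = list(phylum_means = means, ranked = ranked))
}

build_gam_formula <- function(response, smooth_terms, linear_terms,
                              k, random = character(0)) {
  rhs <- c(
    linear_terms,
    vapply(smooth_terms, function(v) sprintf("s(%s, bs = \"cr\", k = %d)", v, k),
           character(1)),
    random
  )
  if (!length(rhs)) rhs <- "1"
  as.formula(paste(response, "~", paste(rhs, collapse = " + ")))
}

#' Fit a generalized additive model
#'
#' Penalized cubic regression splines for the smooth terms with smoothness
#' selected by REML (default) or ML; this realizes models of the form
#' `y = b0 + s(x) + e` such as AAUB on a smooth of CUB.
#'
#' @param data Data frame/tibble with all variables.
#' @param response Response column name.
#' @param smooth_terms Character vector of columns modelled with splines.
#' @param linear_terms Character vector of columns entering linearly.
#' @param k Spline basis dimension (default 10).
#' @param method Smoothness criterion: `"REML"` (default) or `"ML"`.
#' @return A `cb_fit`; `smooth_estimates` holds each fitted curve on a
#'   100-point grid with a 2-standard-error band.
#' @export
fit_gam <- function(data, response, smooth_terms, linear_terms = character(0),
                    k = 10, method = c("REML", "ML")) {
  method <- match.arg(method)
  for (v in smooth_terms) {
    if (var(data[[v]]) == 0) abort(paste0("smooth covariate is constant: ", v))
  }
  if (nrow(data) <= k * length(smooth_terms) + length(linear_terms) + 1L) {
    abort("degenerate model: fewer observations than coefficients")
  }
  df <- as.data.frame(data)
  if (var(df[[response]]) == 0) {
    # degenerate response: the smooth is flat by definition (REML is
    # undefined at zero deviance, so the intercept fit uses the default
    # criterion)
    fml <- as.formula(paste(response, "~ 1"))
    model <- mgcv::gam(fml, data = df)
    return(new_cb_fit(model, kind = "gam", method = method,
                      response = response, data = df))
  }
  fml <- build_gam_formula(response, smooth_terms, linear_terms, k)
  model <- mgcv::gam(fml, data = df, method = method)
  new_cb_fit(model, kind = "gam", method = method, response = response, data = df)
}

# Join profiles to taxonomy and build the strictly nested grouping factors.
prepare_hierarchy <- function(data, taxonomy,
                              hierarchy = c("phylum", "genus", "species")) {
  if (!all(hierarchy %in% names(data))) {
    if (is.null(taxonomy)) abort("taxonomy required (hierarchy columns absent)")
    data <- left_join(data, taxonomy, by = "genome_id")
  }
  miss <- is.na(data[[hierarchy[1]]])
  if (any(miss)) {
    abort(paste0("genomes missing from taxonomy: ",
                 paste(head(data$genome_id[miss], 5), collapse = ", ")))
  }
  # nested labels: a group at level d is identified by its full path, so
  # genomes with missing intermediate labels become singleton groups
  lab <- ""
  for (d in seq_along(hierarchy)) {
    col <- data[[hierarchy[d]]]
    col[is.na(col) | col == ""] <- paste0("._singleton_", which(is.na(col) | col == ""))
    lab <- paste(lab, col, sep = "/")
    data[[paste0(".grp_", hierarchy[d])]] <- factor(lab)
  }
  data
}

#' Fit a hierarchical random-slope GAMM
#'
#' Additive model with the fixed structure of [fit_gam()] plus nested
#' random effects: at each taxonomy level (default phylum, genus,
#' species/strain) a random intercept and an independent random slope on a
#' covariate (default genomic %AT). Groups are identified by their full
#' taxonomic path, so the hierarchy is strictly nested by construction.
#' Fitting goes through [mgcv::gamm()], which estimates smooths and
#' variance components jointly in a nested [nlme::lme()] model; variance
#' components are reported as standard deviations per level and effect.
#' Non-converged fits are returned flagged (`converged = FALSE`) rather
#' than erroring.
#'
#' @inheritParams fit_gam
#' @param taxonomy Taxonomy tibble (joined by `genome_id`) unless the
#'   hierarchy columns are already in `data`.
#' @param hierarchy Ordered hierarchy column names, outermost first.
#' @param slope_var Covariate carrying the random slopes (default
#'   `"at_fraction"`).
#' @return A `cb_fit` with `random_variances` filled in and the underlying
#'   `lme` fit attached.
#' @export
fit_gamm <- function(data, response, smooth_terms = character(0),
                     linear_terms = character(0), taxonomy = NULL,
                     hierarchy = c("phylum", "genus", "species"),
                     slope_var = "at_fraction", k = 10,
                     method = c("REML", "ML")) {
  method <- match.arg(method)
  df <- prepare_hierarchy(as.data.frame(data), taxonomy, hierarchy)
  grp_cols <- paste0(".grp_", hierarchy)
  for (g in grp_cols) {
    if (nlevels(df[[g]]) < 2L) {
      abort(paste0("need at least 2 groups at level ", sub("^\\.grp_", "", g)))
    }
  }
  for (v in smooth_terms) {
    if (var(df[[v]]) == 0) abort(paste0("smooth covariate is constant: ", v))
  }
  slope_fml <- as.formula(paste("~", slope_var))
  random <- setNames(lapply(grp_cols, function(g) nlme::pdDiag(slope_fml)),
                     grp_cols)
  fml <- build_gam_formula(response, smooth_terms, linear_terms, k)
  # allow.n.lt.q: leaf-level groups routinely hold fewer genomes than the
  # two random effects (intercept + slope) they carry; the penalized fit
  # is still well defined
  ctrl <- nlme::lmeControl(returnObject = TRUE, allow.n.lt.q = TRUE)
  model <- tryCatch(
    if (length(smooth_terms)) {
      suppressWarnings(mgcv::gamm(fml, random = random, data = df,
                                  method = method, control = ctrl,
                                  verbosePQL = FALSE))
    } else {
      # no penalized smooth: the model is a plain nested linear mixed model
      list(gam = NULL,
           lme = nlme::lme(fml, random = random, data = df, method = method,
                           control = ctrl))
    },
    error = function(e) e
  )
  if (inherits(model, "error")) {
    warn(paste0("GAMM did not converge: ", conditionMessage(model)))
    return(structure(list(model = NULL, lme = NULL, kind = "gamm",
                          method = method, response = response, data = df,
                          smooth_estimates = NULL, random_variances = NULL,
                          aic = NA_real_, r_squared = NA_real_,
                          converged = FALSE,
                          diagnostics = conditionMessage(model),
                          hierarchy = hierarchy, slope_var = slope_var,
                          smooth_terms = smooth_terms,
                          linear_terms = linear_terms),
                     class = "cb_fit"))
  }
  new_cb_fit(model, kind = "gamm", method = method,
             response = response, data = df,
             extra = list(hierarchy = hierarchy, slope_var = slope_var,
                          smooth_terms = smooth_terms,
                          linear_terms = linear_terms))
}

#' AAUB on a smooth of CUB (fixed-effects additive model)
#'
#' @param profiles Profile tibble with `aaub` and `cub`.
#' @inheritParams fit_gam
#' @return A `cb_fit`.
#' @export
fit_aaub_cub_gam <- function(profiles, k = 10, method = "REML") {
  fit_gam(profiles, "aaub", smooth_terms = "cub", k = k, method = method)
}

#' AAUB on a smooth of CUB with hierarchical %AT random slopes
#'
#' @param profiles Profile tibble with `aaub`, `cub`, `at_fraction`.
#' @inheritParams fit_gamm
#' @return A `cb_fit`.
#' @export
fit_aaub_cub_gamm <- function(profiles, taxonomy = NULL, k = 10, method = "REML") {
  fit_gamm(profiles, "aaub", smooth_terms = "cub", taxonomy = taxonomy,
           k = k, method = method)
}

#' KL relative entropy on %AT and AAUB with hierarchical random slopes
#'
#' The relative-entropy model: KL as response, genomic %AT as a smooth
#' term, AAUB as a linear term, and nested phylum/genus/species random
#' intercepts and %AT slopes.
#'
#' @param profiles Profile tibble with `kl`, `aaub`, `at_fraction`.
#' @inheritParams fit_gamm
#' @return A `cb_fit`.
#' @export
fit_kl_gamm <- function(profiles, taxonomy = NULL, k = 10, method = "REML") {
  fit_gamm(profiles, "kl", smooth_terms = "at_fraction",
           linear_terms = "aaub", taxonomy = taxonomy, k = k, method = method)
}

#' KL relative entropy against genome size
#'
#' GAMM of KL on genome size (linear fixed effect, in megabases for
#' numerical balance) with the standard nested random structure; reports
#' the size-term p-value, the test of whether relative entropy tracks
#' genome size once taxonomy is accounted for.
#'
#' @param profiles Profile tibble with `kl`, `genome_size`, `at_fraction`.
#' @inheritParams fit_gamm
#' @return A `cb_fit` with extra element `size_p_value`.
#' @export
fit_kl_vs_size <- function(profiles, taxonomy = NULL, k = 10, method = "REML") {
  if (nrow(profiles) < 10L) abort("need at least 10 genomes")
  if (var(profiles$genome_size) == 0) abort("degenerate model: constant genome size")
  profiles$size_mb <- profiles$genome_size / 1e6
  fit <- fit_gamm(profiles, "kl", linear_terms = "size_mb",
                  taxonomy = taxonomy, k = k, method = method)
  td <- tidy(fit)
  fit$size_p_value <- td$p_value[td$term == "size_mb"]
  fit
}

# Refit by maximum likelihood, through lme in both cases so the two AICs
# in a comparison come from the same likelihood family. A pure GAM is
# refitted as a gamm without random terms (its smooth becomes an lme
# variance component, fixed terms unchanged).
refit_ml_lme <- function(fit) {
  if (fit$kind == "gamm") {
    if (fit$method == "ML" && !is.null(fit$lme)) return(fit$lme)
    refit <- fit_gamm(fit$data, fit$response, smooth_terms = fit$smooth_terms,
                      linear_terms = fit$linear_terms, hierarchy = fit$hierarchy,
                      slope_var = fit$slope_var, method = "ML")
    if (!refit$converged) abort("ML refit did not converge")
    refit$lme
  } else if (fit$kind == "gam") {
    model <- suppressWarnings(mgcv::gamm(fit$model$formula, data = fit$data,
                                         method = "ML"))
    model$lme
  } else {
    abort("AIC comparison is defined for gam/gamm fits")
  }
}

#' Compare two fits by AIC
#'
#' Both models must be fitted to the identical response vector. Fits are
#' refitted by maximum likelihood through the same mixed-model likelihood
#' before comparison, since REML likelihoods are not comparable across
#' fixed-effect structures. Non-converged fits are rejected.
#'
#' @param fit_a,fit_b `cb_fit` objects for the same observations.
#' @param labels Names used in the report.
#' @return One-row tibble: `preferred`, `delta_aic` (AIC(a) - AIC(b)),
#'   `aic_a`, `aic_b`.
#' @export
compare_aic <- function(fit_a, fit_b, labels = c("model_a", "model_b")) {
  if (!fit_a$converged || !fit_b$converged) {
    abort("cannot compare AIC of a non-converged fit")
  }
  ya <- fit_a$data[[fit_a$response]]
  yb <- fit_b$data[[fit_b$response]]
  if (length(ya) != length(yb) || max(abs(sort(ya) - sort(yb))) > 1e-12) {
    abort("fits are not on the same response observations")
  }
  aa <- AIC(refit_ml_lme(fit_a))
  ab <- AIC(refit_ml_lme(fit_b))
  tibble(preferred = labels[if (aa <= ab) 1L else 2L],
         delta_aic = aa - ab, aic_a = aa, aic_b = ab)
}

#' @export
print.cb_fit <- function(x, ...) {
  if (is.null(x$model)) {
    cat(sprintf("<cb_fit: %s, %s> NON-CONVERGED: %s\n",
                x$kind, x$method, x$diagnostics %||% "unknown"))
    return(invisible(x))
  }
  cat(sprintf("<cb_fit: %s, %s> response: %s, n = %d\n",
              x$kind, x$method, x$response, length(resid(x$model))))
  cat(sprintf("  AIC = %.2f, R^2/dev.expl = %.4f, converged = %s\n",
              x$aic, x$r_squared, x$converged))
  if (!is.null(x$random_variances)) {
    cat("  random-effect std devs:\n")
    rv <- x$random_variances
    for (i in seq_len(nrow(rv))) {
      cat(sprintf("    %-28s %.5g\n", rv$term[i], rv$std_dev[i]))
    }
  }
  invisible(x)
}

#' Tidy a model fit
#'
#' Parametric coefficients (estimate, standard error, p-value) and, for
#' additive models, smooth-term summaries (edf, test statistic, p-value).
#'
#' @param x A `cb_fit`.
#' @param ... Unused.
#' @return A tibble with one row per term.
#' @exportS3Method generics::tidy
#' @export
tidy.cb_fit <- function(x, ...) {
  if (inherits(x$model, "lme")) {
    tt <- summary(x$model)$tTable
    out <- as_tibble(tt, rownames = "term")
    names(out) <- c("term", "estimate", "std_error", "df", "statistic", "p_value")
    out$type <- "parametric"
    out
  } else if (inherits(x$model, "gam")) {
    s <- summary(x$model)
    para <- as_tibble(s$p.table, rownames = "term")
    names(para) <- c("term", "estimate", "std_error", "statistic", "p_value")
    para$type <- "parametric"
    if (!is.null(s$s.table) && nrow(s$s.table)) {
      sm <- as_tibble(s$s.table, rownames = "term")
      names(sm) <- c("term", "edf", "ref_df", "statistic", "p_value")
      sm$type <- "smooth"
      return(bind_rows(para, sm))
    }
    para
  } else {
    s <- summary(x$model)
    out <- as_tibble(s$coefficients, rownames = "term")
    names(out) <- c("term", "estimate", "std_error", "statistic", "p_value")
    out$type <- "parametric"
    out
  }
}

#' @rdname tidy.cb_fit
#' @return `glance()`: a one-row tibble with `aic`, `r_squared`,
#'   `n`, `method`, `converged`.
#' @exportS3Method generics::glance
#' @export
glance.cb_fit <- function(x, ...) {
  tibble(aic = x$aic, r_squared = x$r_squared,
         n = if (is.null(x$model)) nrow(x$data) else length(resid(x$model)),
         method = x$method, kind = x$kind, converged = x$converged)
}

#' Plot fitted smooth terms with a 2-SE band
#'
#' @param object A `cb_fit` with smooth terms.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.cb_fit <- function(object, ...) {
  sm <- object$smooth_estimates
  if (is.null(sm)) abort("fit has no univariate smooth terms to plot")
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$x, y = .data$fit)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(x = NULL, y = "Partial effect") +
    ggplot2::theme_minimal()
}
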