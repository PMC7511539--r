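# Rank-based longitudinal mixed-effects analysis.
#
# The response is replaced by mid-ranks computed over ALL observations, a
# linear mixed model with a participant random intercept is fitted to the
# ranks (lme4), and fixed effects are tested with Type III Wald F statistics
# under sum-to-zero contrasts. Denominator degrees of freedom follow the
# containment scheme: effects that are constant within participants
# (between-subject: group, musical training) are tested against the subject
# stratum (n_subjects - between-effect parameters), effects that vary within
# participants (session, block, their group interactions) against the
# within-subject residual (N - n_subjects - within-effect parameters). With
# 25 participants and 4 sessions this yields the familiar F(3, 69) /
# F(1, 22) df shapes of such analyses. If the highest-order group
# interaction is not significant it is dropped and the model refitted
# (model-reduction rule); least-squares means contrasts are computed on the
# rank scale without multiplicity adjustment.

term_vars <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]

varies_within_subject <- function(data, var, subject) {
  v <- split(data[[var]], data[[subject]])
  any(vapply(v, function(z) length(unique(z)) > 1L, TRUE))
}

#' Fit a rank-based longitudinal mixed model
#'
#' @param data Long-format table with one row per analysis unit (typically
#'   one per participant x session or participant x block summary).
#' @param response Column to analyze (e.g. `"pitch_accuracy"`).
#' @param fixed Character vector of fixed-effect terms, `":"` for
#'   interactions, e.g. `c("group", "session", "group:session")`. Character
#'   columns are converted to factors.
#' @param covariate Optional numeric covariate column (default
#'   `"musical_training"`; `NULL` for none).
#' @param subject Grouping column for the random intercept (default
#'   `"participant_id"`).
#' @param reduce Drop a non-significant (p > `alpha`) highest-order
#'   interaction and refit with main effects only (default `TRUE`).
#' @param contrast Optional factor name (or `"factorA|factorB"` for
#'   conditioning) for pairwise least-squares contrasts on the rank scale.
#' @param alpha Significance level used by the reduction rule (0.05).
#' @return An object of class `"rank_mixed_model"`: list with `effects`
#'   (tibble: term, F, df_num, df_den, p, stage full/reduced), `contrasts`
#'   (tibble or NULL), `fit` (the final lmerMod on ranks), `reduced`
#'   (logical), `response`, `lsmeans` (rank-scale least-squares means) and
#'   `cell_means` (raw-response cell means of the contrast factor, for
#'   back-transformed reporting).
#' @examples
#' cfg <- cohort_config(n_hiit = 6, n_liit = 6, seed = 3,
#'                      phases = c("acquisition", "retention"))
#' sess <- summarize_sessions(simulate_study(cfg))
#' m <- rank_mixed_model(sess, "pitch_accuracy",
#'                       c("group", "session", "group:session"))
#' m$effects
#' @export
rank_mixed_model <- function(data, response,
                             fixed = c("group", "session", "group:session"),
                             covariate = "musical_training",
                             subject = "participant_id",
                             reduce = TRUE, contrast = NULL, alpha = 0.05) {
  data <- as.data.frame(data)
  if (!response %in% names(data)) stop("unknown response: ", response, call. = FALSE)
  factor_vars <- unique(unlist(lapply(fixed, term_vars)))
  for (v in factor_vars) {
    if (!v %in% names(data)) stop("unknown fixed-effect variable: ", v, call. = FALSE)
    if (!is.numeric(data[[v]])) data[[v]] <- factor(data[[v]])
    if (is.factor(data[[v]]) && nlevels(droplevels(data[[v]])) < 2L)
      stop("fixed factor '", v, "' has fewer than 2 observed levels", call. = FALSE)
  }
  # empty-cell check for interactions
  for (tm in fixed[grepl(":", fixed)]) {
    vs <- term_vars(tm)
    if (all(vapply(vs, function(v) is.factor(data[[v]]), TRUE))) {
      tab <- table(data[vs])
      if (any(tab == 0))
        stop("rank-deficient design: empty cell in ", tm, " at ",
             paste(names(which(tab == 0))[1], collapse = ":"), call. = FALSE)
    }
  }
  data[[subject]] <- factor(data[[subject]])
  data$.rank <- rank(data[[response]], ties.method = "average")

  fit_model <- function(terms) {
    rhs <- paste(c(terms, covariate), collapse = " + ")
    f <- stats::as.formula(paste0(".rank ~ ", rhs, " + (1 | ", subject, ")"))
    old <- options(contrasts = c("contr.sum", "contr.poly"))
    on.exit(options(old))
    suppressMessages(lme4::lmer(f, data = data, REML = TRUE,
                                control = lme4::lmerControl(calc.derivs = FALSE,
                                                            check.conv.singular = "ignore",
                                                            check.nobs.vs.nlev = "ignore",
                                                            check.nobs.vs.nRE = "ignore")))
  }

  type3_table <- function(fit, terms, stage) {
    X <- lme4::getME(fit, "X")
    asgn <- attr(X, "assign")
    labs <- attr(stats::terms(fit, fixed.only = TRUE), "term.labels")
    b <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    n_subj <- nlevels(data[[subject]])
    N <- nrow(data)
    within <- vapply(labs, function(tm)
      any(vapply(term_vars(tm), varies_within_subject, TRUE,
                 data = data, subject = subject)), TRUE)
    p_within <- sum(vapply(which(within), function(i) sum(asgn == i), 0L))
    p_between <- sum(vapply(which(!within), function(i) sum(asgn == i), 0L))
    df_den_within <- N - n_subj - p_within
    df_den_between <- n_subj - 1L - p_between
    rows <- lapply(seq_along(labs), function(i) {
      idx <- which(asgn == i)
      Fst <- drop(t(b[idx]) %*% solve(V[idx, idx, drop = FALSE]) %*% b[idx]) / length(idx)
      dfd <- if (within[i]) df_den_within else df_den_between
      tibble::tibble(term = labs[i], F = Fst, df_num = length(idx),
                     df_den = dfd,
                     p = stats::pf(Fst, length(idx), dfd, lower.tail = FALSE),
                     stage = stage)
    })
    dplyr::bind_rows(rows)
  }

  fit_full <- fit_model(fixed)
  eff_full <- type3_table(fit_full, fixed, "full")
  inter_terms <- fixed[grepl(":", fixed)]
  reduced <- FALSE
  fit_final <- fit_full
  effects <- eff_full
  if (reduce && length(inter_terms)) {
    top <- inter_terms[which.max(lengths(lapply(inter_terms, term_vars)))]
    p_top <- eff_full$p[eff_full$term == top]
    if (length(p_top) == 1 && p_top > alpha) {
      keep <- setdiff(fixed, top)
      fit_final <- fit_model(keep)
      effects <- dplyr::bind_rows(
        eff_full[eff_full$term == top, ],
        type3_table(fit_final, keep, "reduced"))
      reduced <- TRUE
    }
  }

  contrasts_tbl <- NULL
  lsm <- NULL
  cell_means <- NULL
  if (!is.null(contrast)) {
    parts <- term_vars(gsub("\\|", ":", contrast))
    by_var <- if (grepl("|", contrast, fixed = TRUE)) parts[2] else NULL
    spec <- stats::as.formula(paste0("~ ", gsub("\\|", " | ", contrast)))
    emm <- suppressMessages(
      emmeans::emmeans(fit_final, spec, lmer.df = "asymptotic"))
    ctr <- summary(emmeans::contrast(emm, method = "pairwise", adjust = "none"),
                   infer = FALSE)
    # containment df for the contrast factor
    n_subj <- nlevels(data[[subject]])
    N <- nrow(data)
    X <- lme4::getME(fit_final, "X")
    asgn <- attr(X, "assign")
    labs <- attr(stats::terms(fit_final, fixed.only = TRUE), "term.labels")
    within_named <- vapply(labs, function(tm)
      any(vapply(term_vars(tm), varies_within_subject, TRUE,
                 data = data, subject = subject)), TRUE)
    p_within <- sum(vapply(which(within_named), function(i) sum(asgn == i), 0L))
    p_between <- sum(vapply(which(!within_named), function(i) sum(asgn == i), 0L))
    cf_within <- varies_within_subject(data, parts[1], subject)
    dfd <- if (cf_within) N - n_subj - p_within else n_subj - 1L - p_between
    tstat <- ctr$estimate / ctr$SE
    contrasts_tbl <- tibble::tibble(
      contrast = as.character(ctr$contrast),
      estimate = ctr$estimate, se = ctr$SE, t = tstat, df = dfd,
      p = 2 * stats::pt(-abs(tstat), dfd))
    if (!is.null(by_var)) contrasts_tbl[[by_var]] <- ctr[[by_var]]
    lsm <- tibble::as_tibble(summary(emm, infer = FALSE))
    cms <- split(data[[response]],
                 interaction(data[parts], drop = TRUE, sep = " "))
    cell_means <- tibble::tibble(cell = names(cms),
                                 mean = vapply(cms, mean, 0),
                                 sd = vapply(cms, stats::sd, 0))
  }

  structure(
    list(effects = effects, contrasts = contrasts_tbl, lsmeans = lsm,
         cell_means = cell_means, fit = fit_final, reduced = reduced,
         response = response, alpha = alpha),
    class = "rank_mixed_model")
}

#' @exportS3Method print rank_mixed_model
print.rank_mixed_model <- function(x, ...) {
  cat("Rank-based mixed model on", x$response,
      if (x$reduced) "(interaction dropped, model refitted)" else "", "\n")
  eff <- x$effects
  for (i in seq_len(nrow(eff)))
    cat(sprintf("  %-28s F(%d, %d) = %6.2f, p = %.4g  [%s]\n",
                eff$term[i], eff$df_num[i], eff$df_den[i], eff$F[i],
                eff$p[i], eff$stage[i]))
  if (!is.null(x$contrasts)) {
    cat("  Least-squares contrasts (rank scale, unadjusted):\n")
    print(x$contrasts, n = 10)
  }
  invisible(x)
}

#' Per-group linear trends over block
#'
#' Least-squares per-group slopes of the raw accuracy over block (block
#' treated as numeric), within a mixed-model framework: the model
#' `response ~ group * block + covariate + (1 | subject)` is fitted on the
#' raw percent scale and per-group trends extracted, reported in percentage
#' points per block.
#'
#' @param data Block-level table (see [summarize_blocks()]) with a numeric
#'   or integer `block` column covering at least 3 blocks.
#' @param response Column to analyze.
#' @param covariate,subject As in [rank_mixed_model()].
#' @return A list with `slopes` (tibble: group, slope, se) and `difference`
#'   (tibble: estimate, se, t, df, p for the slope difference), plus `fit`.
#' @export
block_slopes <- function(data, response, covariate = "musical_training",
                         subject = "participant_id") {
  data <- as.data.frame(data)
  if (length(unique(data$block)) < 3L)
    stop("trend over block needs at least 3 blocks", call. = FALSE)
  data$group <- factor(data$group)
  data[[subject]] <- factor(data[[subject]])
  data$block <- as.numeric(data$block)
  data$.y <- data[[response]]
  rhs <- paste(c("group * block", covariate), collapse = " + ")
  f <- stats::as.formula(paste0(".y ~ ", rhs, " + (1 | ", subject, ")"))
  fit <- suppressMessages(lme4::lmer(f, data = data, REML = TRUE,
                                     control = lme4::lmerControl(calc.derivs = FALSE,
                                                                 check.conv.singular = "ignore",
                                                                 check.nobs.vs.nlev = "ignore",
                                                                 check.nobs.vs.nRE = "ignore")))
  trends <- suppressMessages(
    emmeans::emtrends(fit, "group", var = "block", lmer.df = "asymptotic"))
  emt <- summary(trends, infer = FALSE)
  slopes <- tibble::tibble(group = as.character(emt$group),
                           slope = emt$block.trend, se = emt$SE)
  dctr <- summary(emmeans::contrast(trends, method = "pairwise",
                                    adjust = "none"), infer = FALSE)
  n_subj <- nlevels(data[[subject]])
  N <- nrow(data)
  dfd <- N - n_subj - 2L   # block + group:block columns
  tstat <- dctr$estimate / dctr$SE
  difference <- tibble::tibble(contrast = as.character(dctr$contrast),
                               estimate = dctr$estimate, se = dctr$SE,
                               t = tstat, df = dfd,
                               p = 2 * stats::pt(-abs(tstat), dfd))
  list(slopes = slopes, difference = difference, fit = fit)
}
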