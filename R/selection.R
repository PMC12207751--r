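## Model selection: concurvity screening of smooth terms, all-subsets AIC
## selection over groups of collinear covariates, and the two modelling
## studies — the survey-altitude detectability model on dual-surveyed cells
## and the full distribution model.

#' Concurvity screen of a fitted model's smooth terms
#'
#' For every term, the worst-case concurvity with every other term: the
#' square of the largest canonical correlation between the term's design
#' columns and the span of the other term's columns (0 = orthogonal spans,
#' 1 = the term lies entirely inside the other's span). Terms are grouped
#' by transitive closure over pairs exceeding `threshold`.
#'
#' @param fit a [dsm_gam()] fit.
#' @param threshold pairing threshold on the pairwise measure (default 0.8).
#' @return list with `matrix` (pairwise worst concurvity), `groups` (list of
#'   character vectors of term labels, only groups of >= 2), and `threshold`.
#' @export
concurvity_screen <- function(fit, threshold = 0.8) {
  des <- fit$design
  labs <- names(des$term_cols)
  Q <- lapply(labs, function(l) {
    M <- des$X[, des$term_cols[[l]], drop = FALSE]
    M <- sweep(M, 2, colMeans(M))
    qr_ <- qr(M)
    qr.Q(qr_)[, seq_len(qr_$rank), drop = FALSE]
  })
  k <- length(labs)
  C <- matrix(0, k, k, dimnames = list(labs, labs))
  if (k > 1) {
    for (a in 1:(k - 1)) for (b in (a + 1):k) {
      s <- svd(crossprod(Q[[a]], Q[[b]]), nu = 0, nv = 0)$d
      C[a, b] <- C[b, a] <- min(1, max(s)^2)
    }
  }
  adj <- C > threshold
  comp <- rep(0L, k); cur <- 0L
  for (v in seq_len(k)) {
    if (comp[v] > 0L) next
    cur <- cur + 1L
    stack <- v
    while (length(stack) > 0) {
      u <- stack[[1]]; stack <- stack[-1]
      if (comp[u] > 0L) next
      comp[u] <- cur
      stack <- c(stack, which(adj[u, ] & comp == 0L))
    }
  }
  groups <- split(labs, comp)
  groups <- unname(groups[vapply(groups, length, 0L) >= 2])
  list(matrix = C, groups = groups, threshold = threshold)
}

#' All-subsets AIC selection over a correlated covariate group
#'
#' Refits the model with every subset of the correlated group of smooth
#' terms (uncorrelated terms always retained) and keeps the fit with the
#' lowest AIC, regardless of whether correlated terms survive; ties within
#' 1e-6 AIC go to the candidate with fewer total effective degrees of
#' freedom. Candidates that fail to converge are dropped with a message.
#'
#' @param data model frame.
#' @param smooths full list of smooth specs.
#' @param group character vector of smooth labels forming the correlated
#'   group (an empty group returns the single full fit).
#' @param ... passed to [dsm_gam()] (para, family, gamma, ...).
#' @return a `dsm_selection` list: `fit` (best model), `candidates`
#'   (data.frame of subsets with AIC and edf), `group`.
#' @export
select_by_aic <- function(data, smooths, group, ...) {
  labs <- vapply(smooths, `[[`, "", "label")
  if (length(group) == 0) {
    fit <- dsm_gam(data, smooths = smooths, ...)
    return(structure(list(fit = fit,
                          candidates = data.frame(subset = "(all)",
                                                  aic = fit$aic,
                                                  edf = fit$edf_total),
                          group = character(0)),
                     class = "dsm_selection"))
  }
  if (length(group) > 12) stop_param("correlated group too large (> 12)")
  if (!all(group %in% labs)) stop_param("group labels not among smooth terms")
  keep_always <- smooths[!labs %in% group]
  grp_specs <- smooths[labs %in% group]
  nsub <- 2^length(grp_specs)
  cand <- vector("list", nsub); descr <- character(nsub)
  aic <- rep(Inf, nsub); edf <- rep(NA_real_, nsub)
  for (s in seq_len(nsub) - 1L) {
    inc <- as.logical(bitwAnd(s, 2^(seq_along(grp_specs) - 1L)) > 0)
    sub_specs <- c(keep_always, grp_specs[inc])
    descr[s + 1L] <- if (!any(inc)) "(none)" else
      paste(vapply(grp_specs[inc], `[[`, "", "label"), collapse = " + ")
    ft <- tryCatch(dsm_gam(data, smooths = sub_specs, ...),
                   error = function(e) NULL)
    if (is.null(ft)) { message("candidate '", descr[s + 1L],
                               "' failed to fit; excluded"); next }
    cand[[s + 1L]] <- ft
    aic[s + 1L] <- ft$aic
    edf[s + 1L] <- ft$edf_total
  }
  ok <- is.finite(aic)
  if (!any(ok)) stop_param("no candidate model converged")
  best_aic <- min(aic[ok])
  tied <- which(ok & aic <= best_aic + 1e-6)
  best <- tied[which.min(edf[tied])]
  structure(list(fit = cand[[best]],
                 candidates = data.frame(subset = descr, aic = aic, edf = edf),
                 chosen = descr[best], group = group),
            class = "dsm_selection")
}

#' @export
print.dsm_selection <- function(x, ...) {
  cat("AIC selection over {", paste(x$group, collapse = ", "), "}\n")
  o <- order(x$candidates$aic)
  print(utils::head(x$candidates[o, ], 8), row.names = FALSE)
  invisible(x)
}

default_env_smooths <- function(vars, k = 5)
  lapply(vars, function(v) s_tp(v, k = k))

#' Survey-altitude detectability model
#'
#' Fits the detectability study on the dual-surveyed cells: counts as a
#' function of a bivariate spatial smooth, survey year (factor), a
#' factor-smooth interaction of mean Beaufort sea state by survey altitude,
#' a parametric altitude term (needed because the factor smooths are
#' centred), and shrinkage smooths of the requested environmental
#' covariates, with log effort area as offset. Covariates are screened for
#' concurvity and any correlated group is resolved by all-subsets AIC.
#'
#' @param records dual-altitude (cell x pass) table from
#'   [dual_altitude_subset()], with covariates appended; both altitude
#'   levels must be present.
#' @param env_covariates column names entering as univariate shrinkage
#'   smooths.
#' @param k,k_xy basis dimensions.
#' @param concurvity_threshold pairing threshold for the screen.
#' @param include_year add year as a parametric factor (skipped with a
#'   message when only one year is present).
#' @param ... passed to [dsm_gam()].
#' @return list: `fit` (final model), `selection` (a `dsm_selection`),
#'   `concurvity`, `altitude_coef`, `altitude_p`.
#' @export
altitude_model <- function(records, env_covariates = character(0), k = 5,
                           k_xy = 30, concurvity_threshold = 0.8,
                           include_year = TRUE, ...) {
  if (length(unique(records$altitude)) < 2)
    stop_param("both survey altitudes must be present; use dual_altitude_subset()")
  ## baseline "low": the parametric coefficient is the log detectability
  ## penalty of flying high
  records$altitude <- factor(records$altitude, levels = c("low", "high"))
  para <- "altitude"
  if (include_year && length(unique(records$year)) > 1) {
    records$year <- factor(records$year)
    para <- c(para, "year")
  }
  smooths <- c(list(s_xy(k = k_xy), s_by("mean_ss", "altitude", k = k)),
               default_env_smooths(env_covariates, k))
  fit0 <- dsm_gam(records, smooths = smooths, para = para, ...)
  conc <- concurvity_screen(fit0, concurvity_threshold)
  env_labels <- paste0("s(", env_covariates, ")")
  group <- unique(unlist(lapply(conc$groups, intersect, env_labels)))
  sel <- select_by_aic(records, smooths, group, para = para, ...)
  tt <- sel$fit$term_table
  alt_row <- tt[tt$term == "altitude", ]
  list(fit = sel$fit, selection = sel, concurvity = conc,
       altitude_coef = unname(sel$fit$beta["altitudehigh"]),
       altitude_p = alt_row$p_value)
}

#' Distribution and abundance model
#'
#' Fits the full distribution model on every surveyed (cell x pass) row:
#' the same detectability structure as [altitude_model()] plus shrinkage
#' smooths of all environmental covariates, with year as a random effect.
#' After concurvity-driven AIC selection, a non-significant year effect
#' (p >= 0.05) is dropped and the model refitted, to keep predictions free
#' of year-specific offsets.
#'
#' @inheritParams altitude_model
#' @param records all surveyed rows with covariates appended.
#' @return list: `fit`, `selection`, `concurvity`, `year_dropped`.
#' @export
distribution_model <- function(records, env_covariates, k = 5, k_xy = 30,
                               concurvity_threshold = 0.8, ...) {
  use_alt <- length(unique(records$altitude)) > 1
  if (use_alt)
    records$altitude <- factor(records$altitude, levels = c("low", "high"))
  records$year <- factor(records$year)
  use_year <- nlevels(records$year) > 1
  para <- if (use_alt) "altitude" else character(0)
  ## with a single-altitude design the detectability interaction collapses
  ## to a plain sea-state smooth
  ss_term <- if (use_alt) s_by("mean_ss", "altitude", k = k)
             else s_tp("mean_ss", k = k)
  smooths <- c(list(s_xy(k = k_xy), ss_term),
               default_env_smooths(env_covariates, k),
               if (use_year) list(s_re("year")))
  fit0 <- dsm_gam(records, smooths = smooths, para = para, ...)
  conc <- concurvity_screen(fit0, concurvity_threshold)
  candidates <- c(paste0("s(", env_covariates, ")"), "s(x,y)")
  group <- unique(unlist(lapply(conc$groups, intersect, candidates)))
  ## the spatial smooth is always retained: it absorbs residual spatial
  ## autocorrelation; selection acts on the covariates correlated with it
  group <- setdiff(group, "s(x,y)")
  sel <- select_by_aic(records, smooths, group, para = para, ...)
  fit <- sel$fit
  year_dropped <- FALSE
  if (use_year) {
    tt <- fit$term_table
    yr <- tt[tt$term == "re(year)", ]
    if (nrow(yr) == 1 && yr$p_value >= 0.05) {
      labs <- vapply(fit$smooth_specs, `[[`, "", "label")
      fit <- dsm_gam(records, smooths = fit$smooth_specs[labs != "re(year)"],
                     para = para, ...)
      year_dropped <- TRUE
    }
  }
  list(fit = fit, selection = sel, concurvity = conc,
       year_dropped = year_dropped)
}
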