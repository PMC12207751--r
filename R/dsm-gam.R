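#' Negative-binomial log-likelihood
#'
#' Log-likelihood of counts under the negative binomial parameterised by
#' mean `mu` and size `theta` (variance `mu + mu^2 / theta`); `theta = Inf`
#' gives the Poisson limit.
#'
#' @param y non-negative integer counts.
#' @param mu positive means (recycled).
#' @param theta positive size parameter, or `Inf`.
#' @return scalar log-likelihood.
#' @export
nb_loglik <- function(y, mu, theta) {
  if (any(y < 0) || any(y != round(y))) stop_param("y must be non-negative integers")
  if (any(mu <= 0)) stop_param("mu must be positive")
  if (length(theta) != 1 || theta <= 0) stop_param("theta must be a positive scalar")
  if (is.infinite(theta)) return(sum(stats::dpois(y, mu, log = TRUE)))
  sum(stats::dnbinom(y, size = theta, mu = mu, log = TRUE))
}

nb_deviance <- function(y, mu, theta) {
  t1 <- ifelse(y > 0, y * log(y / mu), 0)
  if (is.infinite(theta)) return(2 * sum(t1 - (y - mu)))
  2 * sum(t1 - (y + theta) * log((y + theta) / (mu + theta)))
}

## Design assembly: intercept + parametric columns + smooth blocks, with
## global penalty bookkeeping (each penalty: label, cols, diagonal values).
assemble_design <- function(data, smooths, para) {
  n <- nrow(data)
  X <- matrix(1, n, 1); colnames(X) <- "(Intercept)"
  para_info <- list(); term_cols <- list()
  for (v in para) {
    z <- data[[v]]
    if (is.null(z)) stop_param("parametric variable '", v, "' not in data")
    if (is.character(z) || is.factor(z)) {
      f <- factor(z)
      M <- stats::model.matrix(~ f)[, -1, drop = FALSE]
      colnames(M) <- paste0(v, levels(f)[-1])
      para_info[[v]] <- list(kind = "factor", levels = levels(f))
    } else {
      M <- matrix(z, ncol = 1); colnames(M) <- v
      para_info[[v]] <- list(kind = "numeric")
    }
    term_cols[[v]] <- ncol(X) + seq_len(ncol(M))
    X <- cbind(X, M)
  }
  penalties <- list(); smooth_infos <- list()
  for (sm in smooths) {
    b <- build_basis(sm, data)
    off <- ncol(X)
    for (p in b$penalties) {
      p$cols <- p$cols + off
      penalties[[length(penalties) + 1L]] <- p
    }
    if (identical(b$info$type, "by")) {
      st <- b$info$setup
      q_lv <- ncol(b$X) / length(b$info$levels)
      for (li in seq_along(b$info$levels))
        term_cols[[paste0("s(", b$info$vars, "):", b$info$by,
                          b$info$levels[li])]] <-
          off + (li - 1L) * q_lv + seq_len(q_lv)
    } else {
      term_cols[[b$label]] <- off + seq_len(ncol(b$X))
    }
    smooth_infos[[b$label]] <- b$info
    cn <- colnames(X)
    X <- cbind(X, b$X)
    colnames(X) <- c(cn, paste0(b$label, ".", seq_len(ncol(b$X))))
  }
  list(X = X, penalties = penalties, term_cols = term_cols,
       para_info = para_info, smooth_infos = smooth_infos)
}

pen_sdiag <- function(p, penalties, lambda) {
  s <- numeric(p)
  for (j in seq_along(penalties))
    s[penalties[[j]]$cols] <- s[penalties[[j]]$cols] +
      lambda[j] * penalties[[j]]$val
  s
}

## Penalized IRLS for the NB/Poisson log-link model at fixed smoothing
## parameters; Fisher weights mu / (1 + mu / theta), working response on
## the link scale, step-halving on the penalized deviance.
pirls <- function(X, y, off, sdiag, theta, wscale, beta = NULL,
                  maxit = 200, tol = 1e-8) {
  p <- ncol(X)
  if (is.null(beta)) {
    beta <- numeric(p)
    beta[1] <- log((sum(y) + 0.5) / sum(exp(off)))
  }
  eta <- drop(X %*% beta) + off
  mu <- pmax(exp(eta), 1e-10)
  pdev <- wscale * nb_deviance(y, mu, theta) + sum(sdiag * beta^2)
  conv <- FALSE
  for (it in seq_len(maxit)) {
    w <- wscale * (if (is.infinite(theta)) mu else mu / (1 + mu / theta))
    z <- (eta - off) + (y - mu) / mu
    A <- crossprod(X, X * w)
    diag(A) <- diag(A) + sdiag
    R <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(R)) {
      diag(A) <- diag(A) + max(diag(A)) * 1e-9
      R <- chol(A)
    }
    beta_new <- backsolve(R, forwardsolve(t(R), crossprod(X, w * z)))
    step <- 1
    repeat {
      bb <- beta + step * (beta_new - beta)
      eta_t <- drop(X %*% bb) + off
      if (max(eta_t) > 50) { step <- step / 2
        if (step < 1e-10) stop_param("divergence: infinite fitted mean (separation?)")
        next }
      mu_t <- pmax(exp(eta_t), 1e-10)
      pdev_t <- wscale * nb_deviance(y, mu_t, theta) + sum(sdiag * bb^2)
      if (is.finite(pdev_t) && pdev_t <= pdev + 1e-10) break
      step <- step / 2
      if (step < 1e-10) break
    }
    done <- abs(pdev - pdev_t) < tol * (abs(pdev_t) + 0.1) && it > 1
    beta <- drop(bb); eta <- eta_t; mu <- mu_t; pdev <- pdev_t
    if (done) { conv <- TRUE; break }
  }
  w <- wscale * (if (is.infinite(theta)) mu else mu / (1 + mu / theta))
  A0 <- crossprod(X, X * w)
  A <- A0; diag(A) <- diag(A) + sdiag
  R <- tryCatch(chol(A), error = function(e) {
    diag(A) <- diag(A) + max(diag(A)) * 1e-9; chol(A)
  })
  list(beta = beta, mu = mu, eta = eta, XtWX = A0, R = R,
       dev = nb_deviance(y, mu, theta), conv = conv)
}

## Laplace-approximate REML score of the working penalized fit (additive
## constants dropped): -l/gamma + pen/2 + log|H + S|/2 - log|S|_+/2, with
## every penalty diagonal so the generalized determinant is a sum of logs.
reml_score <- function(ft, y, theta, wscale, sdiag, beta) {
  pen <- sum(sdiag * beta^2)
  sp <- sdiag[sdiag > 0]
  -wscale * nb_loglik(y, ft$mu, theta) + pen / 2 +
    sum(log(diag(ft$R))) - sum(log(sp)) / 2
}

## Extended Fellner-Schall REML updates of the smoothing parameters; each
## coordinate is touched by exactly one (diagonal) penalty, so the
## generalized-determinant traces are closed form. The multiplicative
## update is step-halved on the REML score, which removes the period-2
## oscillation the raw update can fall into.
efs_fit <- function(X, y, off, penalties, theta, wscale, lambda = NULL,
                    beta = NULL, maxit = 100, tol = 1e-3) {
  p <- ncol(X)
  if (length(penalties) == 0) {
    ft <- pirls(X, y, off, numeric(p), theta, wscale, beta)
    return(c(ft, list(lambda = numeric(0), efs_iter = 0L)))
  }
  if (is.null(lambda)) lambda <- rep(1, length(penalties))
  sdiag <- pen_sdiag(p, penalties, lambda)
  ft <- pirls(X, y, off, sdiag, theta, wscale, beta)
  beta <- ft$beta
  reml <- reml_score(ft, y, theta, wscale, sdiag, beta)
  for (it in seq_len(maxit)) {
    V <- chol2inv(ft$R)
    dV <- diag(V)
    new_l <- lambda
    for (j in seq_along(penalties)) {
      cols <- penalties[[j]]$cols; val <- penalties[[j]]$val
      num <- length(cols) - lambda[j] * sum(dV[cols] * val)
      den <- sum(val * beta[cols]^2)
      lj <- if (den < 1e-12) lambda[j] * exp(5) else max(num, 0) / den
      ratio <- min(max(lj / lambda[j], exp(-5)), exp(5))
      new_l[j] <- min(max(lambda[j] * ratio, 1e-9), 1e11)
    }
    step <- 1; accepted <- FALSE
    for (h in 1:8) {
      l_try <- exp(log(lambda) + step * (log(new_l) - log(lambda)))
      s_try <- pen_sdiag(p, penalties, l_try)
      ft_try <- pirls(X, y, off, s_try, theta, wscale, beta)
      r_try <- reml_score(ft_try, y, theta, wscale, s_try, ft_try$beta)
      if (is.finite(r_try) && r_try <= reml + 1e-10) {
        accepted <- TRUE; break
      }
      step <- step / 2
    }
    if (!accepted) break
    delta <- max(abs(log(l_try) - log(lambda)))
    lambda <- l_try; ft <- ft_try; beta <- ft$beta; reml <- r_try
    if (delta < tol) break
  }
  ## the REML surface of a shrinkage term is often bimodal, with a second
  ## optimum at full shrinkage; test the boundary for every term and keep
  ## it when it beats the interior solution
  labs <- sub("\\.(wiggle|null)$", "",
              vapply(penalties, `[[`, "", "label"))
  for (L in unique(labs)) {
    idx <- which(labs == L)
    if (all(lambda[idx] >= 1e10)) next
    l_try <- lambda; l_try[idx] <- 1e11
    s_try <- pen_sdiag(p, penalties, l_try)
    ft_try <- pirls(X, y, off, s_try, theta, wscale, beta)
    r_try <- reml_score(ft_try, y, theta, wscale, s_try, ft_try$beta)
    if (is.finite(r_try) && r_try < reml - 1e-8) {
      lambda <- l_try; ft <- ft_try; beta <- ft$beta; reml <- r_try
    }
  }
  c(ft, list(lambda = lambda, efs_iter = it, reml = reml))
}

#' Fit the negative-binomial density surface model
#'
#' Fits a log-link additive count model with the survey-effort offset:
#' penalized thin-plate regression splines with null-space shrinkage
#' penalties (so terms can shrink to zero effective degrees of freedom and
#' drop out of the model), an optional bivariate spatial smooth,
#' factor-smooth detectability interactions, ridge random effects and
#' parametric terms. Smoothing parameters are chosen by REML via extended
#' Fellner-Schall updates, with the likelihood down-weighted by `gamma`
#' (default 1.2) to favour smoother fits; the negative-binomial size
#' `theta` is estimated by outer profile maximisation unless supplied.
#'
#' @param data model frame: one row per (cell x survey pass).
#' @param smooths list of [s_tp()] / [s_xy()] / [s_by()] / [s_re()] specs.
#' @param para character vector of parametric terms (factors or numerics).
#' @param response count column name (individuals per cell-pass).
#' @param offset effort-area column name (km^2, > 0); its log enters the
#'   linear predictor.
#' @param family `"nb"` (default) or `"poisson"`.
#' @param theta fixed NB size; `NULL` to estimate.
#' @param gamma smoothing-criterion inflation (> 1 gives smoother fits).
#' @param sp optional fixed smoothing parameters (one per penalty; each
#'   spline term carries a wiggliness and a null-space penalty).
#' @param control list: `maxit_pirls`, `tol_pirls`, `maxit_efs`, `tol_efs`,
#'   `theta_iter`.
#' @return a `dsm_gam` object with coefficients, covariance, per-term
#'   effective degrees of freedom and Wald tests, AIC, deviance explained,
#'   and everything needed by [predict.dsm_gam()].
#' @export
dsm_gam <- function(data, smooths = list(), para = character(0),
                    response = "count", offset = "effort_km2",
                    family = c("nb", "poisson"), theta = NULL, gamma = 1.2,
                    sp = NULL, control = list()) {
  family <- match.arg(family)
  ctl <- utils::modifyList(list(maxit_pirls = 200, tol_pirls = 1e-8,
                                maxit_efs = 100, tol_efs = 1e-3,
                                theta_iter = 6), control)
  y <- data[[response]]
  if (is.null(y)) stop_param("response column '", response, "' not found")
  if (any(y < 0) || any(y != round(y))) stop_param("counts must be non-negative integers")
  a <- data[[offset]]
  if (is.null(a)) stop_param("offset column '", offset, "' not found")
  if (any(a <= 0)) stop_param("effort areas must be > 0 for modelled rows")
  off <- log(a)
  if (inherits(smooths, "smooth_spec")) smooths <- list(smooths)
  des <- assemble_design(data, smooths, para)
  X <- des$X
  if (any(!is.finite(X))) stop_param("non-finite covariate values in design")
  wscale <- 1 / gamma
  est_theta <- family == "nb" && is.null(theta)
  th <- if (family == "poisson") Inf else theta %||% 1
  lambda <- NULL; beta <- NULL; ft <- NULL
  fixed_sp <- !is.null(sp)
  if (fixed_sp && length(sp) != length(des$penalties))
    stop_param("sp must have length ", length(des$penalties))
  for (t_it in seq_len(if (est_theta) ctl$theta_iter else 1)) {
    ft <- if (fixed_sp) {
      sd0 <- pen_sdiag(ncol(X), des$penalties, sp)
      c(pirls(X, y, off, sd0, th, wscale, beta,
              maxit = ctl$maxit_pirls, tol = ctl$tol_pirls),
        list(lambda = sp, efs_iter = 0L))
    } else efs_fit(X, y, off, des$penalties, th, wscale, lambda, beta,
                   maxit = ctl$maxit_efs, tol = ctl$tol_efs)
    lambda <- ft$lambda; beta <- ft$beta
    if (!est_theta) break
    th_new <- exp(stats::optimize(function(lt)
      nb_loglik(y, ft$mu, exp(lt)), c(log(1e-3), log(1e7)),
      maximum = TRUE, tol = 1e-6)$maximum)
    if (abs(log(th_new) - log(th)) < 1e-2) { th <- th_new; break }
    th <- th_new
  }
  if (!ft$conv) warning("PIRLS did not fully converge")
  p <- ncol(X)
  sdiag <- pen_sdiag(p, des$penalties, ft$lambda)
  V <- chol2inv(ft$R)              # (X'WX / gamma + S)^-1
  cov_beta <- V / gamma            # = (X'WX + gamma S)^-1
  F_diag <- rowSums(V * ft$XtWX)   # edf per coefficient
  ## null model (intercept + offset only), same theta
  ft0 <- pirls(X[, 1, drop = FALSE], y, off, 0, th, wscale)
  dev0 <- ft0$dev
  edf_term <- vapply(des$term_cols, function(cl) sum(F_diag[cl]), 0)
  edf_total <- sum(F_diag)
  ll <- nb_loglik(y, ft$mu, th)
  aic <- -2 * ll + 2 * (edf_total + if (est_theta) 1 else 0)
  term_table <- term_tests(des, ft$beta, cov_beta, edf_term)
  names(ft$lambda) <- vapply(des$penalties, `[[`, "", "label")
  structure(list(
    beta = stats::setNames(ft$beta, colnames(X)), cov_beta = cov_beta,
    lambda = ft$lambda, theta = th, theta_estimated = est_theta,
    gamma = gamma, family = family,
    edf = edf_term, edf_total = edf_total, F_diag = F_diag,
    loglik = ll, aic = aic,
    deviance = ft$dev, null_deviance = dev0,
    dev_expl = 1 - ft$dev / dev0,
    term_table = term_table,
    fitted = ft$mu, linear_predictor = ft$eta, y = y, offset_log = off,
    design = des, response = response, offset_name = offset,
    smooth_specs = smooths, para = para,
    converged = ft$conv, efs_iter = ft$efs_iter,
    n = nrow(data)),
    class = "dsm_gam")
}

## Approximate Wald tests: z-tests on parametric coefficients; for smooth
## blocks a chi-square on a rank-r pseudo-inverse of the coefficient
## covariance, r tied to the term's effective degrees of freedom.
term_tests <- function(des, beta, cov_beta, edf_term) {
  rows <- NULL
  for (lab in names(des$term_cols)) {
    cl <- des$term_cols[[lab]]
    if (lab %in% names(des$para_info)) {
      se <- sqrt(diag(cov_beta)[cl])
      stat <- sum((beta[cl] / se)^2)
      df <- length(cl)
      pv <- stats::pchisq(stat, df, lower.tail = FALSE)
    } else {
      Vt <- cov_beta[cl, cl, drop = FALSE]
      eg <- eigen((Vt + t(Vt)) / 2, symmetric = TRUE)
      r <- min(length(cl), max(1L, round(edf_term[[lab]])))
      pos <- seq_len(r)
      b2 <- drop(crossprod(eg$vectors[, pos, drop = FALSE], beta[cl]))
      stat <- sum(b2^2 / pmax(eg$values[pos], 1e-12))
      df <- r
      pv <- stats::pchisq(stat, df, lower.tail = FALSE)
    }
    rows <- rbind(rows, data.frame(term = lab, edf = edf_term[[lab]],
                                   statistic = stat, df = df, p_value = pv))
  }
  rownames(rows) <- NULL
  rows
}

#' @export
print.dsm_gam <- function(x, digits = 3, ...) {
  cat(sprintf("Negative-binomial DSM (%s), n = %d\n", x$family, x$n))
  cat(sprintf("theta = %.3g%s, gamma = %g, deviance explained = %.1f%%, AIC = %.1f\n",
              x$theta, if (x$theta_estimated) " (estimated)" else "",
              x$gamma, 100 * x$dev_expl, x$aic))
  tt <- x$term_table
  tt$edf <- round(tt$edf, digits); tt$statistic <- round(tt$statistic, digits)
  tt$p_value <- signif(tt$p_value, digits)
  print(tt, row.names = FALSE)
  invisible(x)
}

#' Predict expected counts from a fitted density surface model
#'
#' @param object a [dsm_gam()] fit.
#' @param newdata data.frame with the model covariates.
#' @param offset_km2 effort area per row (km^2); defaults to the model's
#'   offset column in `newdata`. Use the full cell area (16 km^2 for a 4 km
#'   grid) to predict whole-cell abundance.
#' @param se also return the link-scale standard error per row.
#' @param extrapolate allow covariate values outside the training support
#'   (whole-area prediction from surveyed cells requires this); with the
#'   default `FALSE` out-of-support rows are an error.
#' @param ... unused.
#' @return expected count per row, or (with `se = TRUE`) a list with `fit`
#'   and `se_link`.
#' @export
predict.dsm_gam <- function(object, newdata, offset_km2 = NULL, se = FALSE,
                            extrapolate = FALSE, ...) {
  if (is.null(offset_km2)) {
    offset_km2 <- newdata[[object$offset_name]]
    if (is.null(offset_km2)) stop_param("no offset column '",
                                        object$offset_name, "' in newdata")
  }
  if (length(offset_km2) == 1) offset_km2 <- rep(offset_km2, nrow(newdata))
  if (any(offset_km2 <= 0)) stop_param("offsets must be positive areas")
  if (!extrapolate) check_support(object, newdata)
  X <- prediction_design(object, newdata)
  eta <- drop(X %*% object$beta) + log(offset_km2)
  mu <- exp(eta)
  if (!all(is.finite(mu)))
    stop_param("non-finite prediction for row(s) ",
               paste(utils::head(which(!is.finite(mu)), 5), collapse = ", "))
  if (!se) return(mu)
  se_link <- sqrt(pmax(rowSums((X %*% object$cov_beta) * X), 0))
  list(fit = mu, se_link = se_link)
}

prediction_design <- function(object, newdata) {
  des <- object$design
  n <- nrow(newdata)
  X <- matrix(1, n, 1)
  for (v in names(des$para_info)) {
    pi_ <- des$para_info[[v]]
    if (pi_$kind == "factor") {
      f <- factor(newdata[[v]], levels = pi_$levels)
      if (anyNA(f)) stop_param("unknown level of '", v, "' in newdata")
      X <- cbind(X, stats::model.matrix(~ f)[, -1, drop = FALSE])
    } else X <- cbind(X, newdata[[v]])
  }
  for (info in des$smooth_infos) X <- cbind(X, predict_basis(info, newdata))
  X
}

check_support <- function(object, newdata) {
  for (info in object$design$smooth_infos) {
    if (is.null(info$range)) next
    if (info$type == "xy") {
      for (k in 1:2) {
        v <- newdata[[info$vars[k]]]
        if (any(v < info$range[1, k] - 1e-9 | v > info$range[2, k] + 1e-9))
          stop_param("newdata '", info$vars[k], "' outside training support; ",
                     "set extrapolate = TRUE to allow")
      }
    } else {
      v <- newdata[[info$vars]]
      if (any(v < info$range[1] - 1e-9 | v > info$range[2] + 1e-9))
        stop_param("newdata '", info$vars, "' outside training support; ",
                   "set extrapolate = TRUE to allow")
    }
  }
  invisible(TRUE)
}
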