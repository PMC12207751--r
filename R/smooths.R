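## Smooth-term specifications and basis construction for the density
## surface model: thin-plate regression splines with a double (shrinkage)
## penalty, bivariate spatial smooths, centred factor-smooth interactions
## and ridge-penalized random effects. Every penalty is reparameterized to
## a diagonal so that smoothing-parameter selection and the REML
## determinant terms are cheap and exact.

#' Smooth term constructors
#'
#' Build term specifications for [dsm_gam()]. `s_tp` is a univariate
#' thin-plate regression spline with shrinkage (the penalty null space —
#' the linear trend — carries its own second penalty, so the whole term can
#' shrink to zero effective degrees of freedom). `s_xy` is the analogous
#' bivariate spatial smooth. `s_by` fits one centred smooth of `var` per
#' level of the factor `by` (a factor-smooth interaction, used for the
#' sea-state x survey-altitude detectability term; the level means are not
#' identifiable, hence the companion parametric factor). `s_re` is an
#' i.i.d. Gaussian random effect of a factor, implemented as a
#' ridge-penalized indicator block.
#'
#' @param var,xvar,yvar covariate column name(s).
#' @param k basis dimension: maximum number of knots (default 5; 30 for the
#'   spatial smooth).
#' @param by factor column defining the levels of a factor-smooth.
#' @param label optional term label.
#' @return a `smooth_spec` object.
#' @export
s_tp <- function(var, k = 5, label = NULL) {
  if (k < 3) stop_param("k must be >= 3 for a spline term")
  structure(list(type = "tp", vars = var, k = k,
                 label = label %||% paste0("s(", var, ")")),
            class = "smooth_spec")
}

#' @rdname s_tp
#' @export
s_xy <- function(xvar = "x", yvar = "y", k = 30, label = NULL) {
  if (k < 4) stop_param("k must be >= 4 for a bivariate spline")
  structure(list(type = "xy", vars = c(xvar, yvar), k = k,
                 label = label %||% paste0("s(", xvar, ",", yvar, ")")),
            class = "smooth_spec")
}

#' @rdname s_tp
#' @export
s_by <- function(var, by, k = 5, label = NULL) {
  if (k < 3) stop_param("k must be >= 3 for a spline term")
  structure(list(type = "by", vars = var, by = by, k = k,
                 label = label %||% paste0("s(", var, "):", by)),
            class = "smooth_spec")
}

#' @rdname s_tp
#' @export
s_re <- function(var, label = NULL) {
  structure(list(type = "re", vars = var,
                 label = label %||% paste0("re(", var, ")")),
            class = "smooth_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

eta_tp1 <- function(r) r^3
eta_tp2 <- function(r) { v <- r^2 * log(r); v[r == 0] <- 0; v }

## Raw univariate TPRS pieces: radial basis about k knots with the
## polynomial null space {1, x}; the constant is dropped (absorbed by the
## model intercept) and the wiggly block is projected onto the constraint
## null space Z of T.
tprs_setup_1d <- function(x, k) {
  ux <- sort(unique(x))
  if (length(ux) < k)
    stop_param("fewer distinct covariate values (", length(ux),
               ") than basis dimension k = ", k, "; lower k")
  knots <- as.numeric(quantile7(ux, seq(0, 1, length.out = k)))
  E <- eta_tp1(abs(outer(knots, knots, "-")))
  T_ <- cbind(1, knots)
  Z <- qr.Q(qr(T_), complete = TRUE)[, 3:k, drop = FALSE]
  S <- crossprod(Z, E %*% Z)
  list(knots = knots, Z = Z, S = (S + t(S)) / 2, m = 2L)
}

tprs_setup_2d <- function(xy, k) {
  u <- unique(xy)
  if (nrow(u) <= k + 1)
    stop_param("fewer distinct locations than basis dimension k = ", k)
  o <- order(u[, 1], u[, 2])
  u <- u[o, , drop = FALSE]
  init <- u[round(seq(1, nrow(u), length.out = k)), , drop = FALSE]
  km <- suppressWarnings(stats::kmeans(u, centers = init, iter.max = 50))
  knots <- km$centers
  r <- sqrt(outer(knots[, 1], knots[, 1], "-")^2 +
              outer(knots[, 2], knots[, 2], "-")^2)
  E <- eta_tp2(r)
  T_ <- cbind(1, knots)
  Z <- qr.Q(qr(T_), complete = TRUE)[, 4:k, drop = FALSE]
  S <- crossprod(Z, E %*% Z)
  list(knots = knots, Z = Z, S = (S + t(S)) / 2, m = 3L)
}

## Evaluate the raw (pre-reparameterization) basis at data: wiggly block
## E(x, knots) %*% Z followed by the polynomial null-space columns
## (without the constant).
tprs_eval_raw <- function(setup, x) {
  if (is.matrix(setup$knots)) {
    r <- sqrt(outer(x[, 1], setup$knots[, 1], "-")^2 +
                outer(x[, 2], setup$knots[, 2], "-")^2)
    cbind(eta_tp2(r) %*% setup$Z, x[, 1], x[, 2])
  } else {
    r <- abs(outer(x, setup$knots, "-"))
    cbind(eta_tp1(r) %*% setup$Z, x)
  }
}

## Reparameterize one spline block to a diagonal penalty: eigen-decompose
## the wiggliness penalty, rotate, append the (unpenalized) polynomial
## columns, centre everything for the sum-to-zero constraint, and rescale
## columns to unit RMS. Returns the design block, the diagonal main and
## null (shrinkage) penalty values, and everything needed to rebuild the
## block at prediction time.
diagonalize_block <- function(Xraw, S, n_null) {
  q_pen <- ncol(S)
  eg <- eigen(S, symmetric = TRUE)
  d <- eg$values
  pos <- d > max(d) * 1e-8
  U <- eg$vectors
  X <- cbind(Xraw[, seq_len(q_pen), drop = FALSE] %*% U,
             Xraw[, -seq_len(q_pen), drop = FALSE])
  d_main <- c(ifelse(pos, pmax(d, 0), 0), rep(0, n_null))
  d_null <- c(ifelse(pos, 0, 1), rep(1, n_null))
  cm <- colMeans(X)
  X <- sweep(X, 2, cm)
  sc <- sqrt(pmax(colMeans(X^2), 1e-300))
  X <- sweep(X, 2, sc, "/")
  d_main <- d_main / sc^2
  d_null <- d_null / sc^2
  list(X = X, d_main = d_main, d_null = d_null, U = U, cm = cm, sc = sc,
       q_pen = q_pen)
}

rebuild_block <- function(info, Xraw) {
  q_pen <- info$q_pen
  X <- cbind(Xraw[, seq_len(q_pen), drop = FALSE] %*% info$U,
             Xraw[, -seq_len(q_pen), drop = FALSE])
  X <- sweep(X, 2, info$cm)
  sweep(X, 2, info$sc, "/")
}

#' Build the design columns and penalties of one smooth term
#'
#' Evaluates a [s_tp()], [s_xy()], [s_by()] or [s_re()] specification on a
#' data frame, returning the centred design block together with the
#' diagonal wiggliness penalty and the null-space shrinkage penalty that
#' allow the whole term to be penalized out of the model.
#'
#' @param spec a `smooth_spec`.
#' @param data data.frame containing the spec's variables.
#' @return list with `X` (design block), `penalties` (list of
#'   `list(label, cols, val)` with local column indices), `info` for
#'   prediction, and `label`.
#' @export
build_basis <- function(spec, data) {
  stopifnot(inherits(spec, "smooth_spec"))
  switch(spec$type,
    tp = {
      x <- data[[spec$vars]]
      st <- tprs_setup_1d(x, spec$k)
      blk <- diagonalize_block(tprs_eval_raw(st, x), st$S, 1L)
      list(X = blk$X, label = spec$label,
           penalties = pen_pair(spec$label, blk),
           info = list(type = "tp", vars = spec$vars, setup = st, blk = blk,
                       range = range(x)))
    },
    xy = {
      xy <- as.matrix(data[spec$vars])
      st <- tprs_setup_2d(xy, spec$k)
      blk <- diagonalize_block(tprs_eval_raw(st, xy), st$S, 2L)
      list(X = blk$X, label = spec$label,
           penalties = pen_pair(spec$label, blk),
           info = list(type = "xy", vars = spec$vars, setup = st, blk = blk,
                       range = apply(xy, 2, range)))
    },
    by = {
      x <- data[[spec$vars]]
      f <- factor(data[[spec$by]])
      if (nlevels(f) < 2) stop_param("'by' factor needs >= 2 levels")
      st <- tprs_setup_1d(x, spec$k)
      Xraw <- tprs_eval_raw(st, x)
      X <- NULL; penalties <- list(); infos <- list()
      for (lv in levels(f)) {
        Xl <- Xraw * (f == lv)
        blk <- diagonalize_block(Xl, st$S, 1L)
        off <- if (is.null(X)) 0L else ncol(X)
        lab <- paste0("s(", spec$vars, "):", spec$by, lv)
        pp <- pen_pair(lab, blk)
        for (p in seq_along(pp)) pp[[p]]$cols <- pp[[p]]$cols + off
        penalties <- c(penalties, pp)
        infos[[lv]] <- blk
        X <- cbind(X, blk$X)
      }
      list(X = X, label = spec$label, penalties = penalties,
           info = list(type = "by", vars = spec$vars, by = spec$by,
                       levels = levels(f), setup = st, blks = infos,
                       range = range(x)))
    },
    re = {
      f <- factor(data[[spec$vars]])
      X <- stats::model.matrix(~ f - 1)
      colnames(X) <- paste0(spec$vars, levels(f))
      list(X = X, label = spec$label,
           penalties = list(list(label = spec$label, cols = seq_len(ncol(X)),
                                 val = rep(1, ncol(X)))),
           info = list(type = "re", vars = spec$vars, levels = levels(f)))
    },
    stop_param("unknown smooth type"))
}

pen_pair <- function(label, blk) {
  main <- which(blk$d_main > 0)
  nul <- which(blk$d_null > 0)
  out <- list()
  if (length(main) > 0)
    out <- c(out, list(list(label = paste0(label, ".wiggle"), cols = main,
                            val = blk$d_main[main])))
  if (length(nul) > 0)
    out <- c(out, list(list(label = paste0(label, ".null"), cols = nul,
                            val = blk$d_null[nul])))
  out
}

## Design block of a fitted term evaluated on new data.
predict_basis <- function(info, data) {
  switch(info$type,
    tp = rebuild_block(info$blk, tprs_eval_raw(info$setup, data[[info$vars]])),
    xy = rebuild_block(info$blk,
                       tprs_eval_raw(info$setup, as.matrix(data[info$vars]))),
    by = {
      f <- factor(data[[info$by]], levels = info$levels)
      if (anyNA(f)) stop_param("unknown level of factor '", info$by, "'")
      Xraw <- tprs_eval_raw(info$setup, data[[info$vars]])
      do.call(cbind, lapply(info$levels, function(lv)
        rebuild_block(info$blks[[lv]], Xraw * (f == lv))))
    },
    re = {
      f <- factor(data[[info$vars]], levels = info$levels)
      if (anyNA(f)) stop_param("unknown level of factor '", info$vars, "'")
      stats::model.matrix(~ f - 1)
    })
}
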