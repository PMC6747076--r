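#' Fit a PLS regression (NIPALS, single response)
#'
#' Sequential latent components extracted from column-centered data by the
#' NIPALS algorithm; deterministic for a fixed row order.  No column
#' autoscaling is applied (CoMFA descriptor tables arrive already
#' block-scaled).  If the requested number of components exceeds the rank
#' of `X` the extraction stops early and the model records a clipping note.
#'
#' @param X numeric design matrix (rows = compounds).
#' @param y numeric response.
#' @param n_components number of latent components to extract.
#' @return object of class `pls_model`: weights `W`, loadings `P`,
#'   y-loadings `Q`, scores `T`, per-component coefficient access, training
#'   means, and regression coefficients on the original columns.
#' @export
fit_pls <- function(X, y, n_components = 2L) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 rows")
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  cap <- min(nrow(X) - 1L, ncol(X))
  if (n_components < 1L) stop("n_components must be >= 1")
  xbar <- colMeans(X); ybar <- mean(y)
  Xc <- sweep(X, 2, xbar); yc <- y - ybar
  A <- min(n_components, cap)
  W <- P <- matrix(0, ncol(X), A)
  Tm <- matrix(0, nrow(X), A)
  Q <- numeric(A)
  clipped <- n_components > cap
  a <- 0L
  for (k in seq_len(A)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { clipped <- TRUE; break }
    w <- w / nw
    t <- drop(Xc %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12) { clipped <- TRUE; break }
    p <- drop(crossprod(Xc, t)) / tt
    q <- sum(yc * t) / tt
    Xc <- Xc - tcrossprod(t, p)
    yc <- yc - q * t
    a <- k
    W[, k] <- w; P[, k] <- p; Tm[, k] <- t; Q[k] <- q
  }
  if (a == 0L) {
    # constant response (or X): intercept-only model
    model <- structure(list(
      n_components = 0L, W = W[, 0, drop = FALSE], P = P[, 0, drop = FALSE],
      Q = numeric(0), scores = Tm[, 0, drop = FALSE],
      xbar = xbar, ybar = ybar,
      coefficients = numeric(ncol(X)), clipped = TRUE,
      colnames = colnames(X)), class = "pls_model")
    return(model)
  }
  W <- W[, 1:a, drop = FALSE]; P <- P[, 1:a, drop = FALSE]
  Tm <- Tm[, 1:a, drop = FALSE]; Q <- Q[1:a]
  if (clipped)
    warning("component extraction stopped at ", a,
            " (requested ", n_components, ")")
  structure(list(
    n_components = a, W = W, P = P, Q = Q, scores = Tm,
    xbar = xbar, ybar = ybar,
    coefficients = pls_coef(W, P, Q, a),
    clipped = clipped, colnames = colnames(X)
  ), class = "pls_model")
}

pls_coef <- function(W, P, Q, k) {
  Wk <- W[, 1:k, drop = FALSE]
  Pk <- P[, 1:k, drop = FALSE]
  drop(Wk %*% solve(crossprod(Pk, Wk), Q[1:k]))
}

#' @export
print.pls_model <- function(x, ...) {
  cat("<pls_model>", x$n_components, "components,",
      length(x$coefficients), "descriptors\n")
  invisible(x)
}

#' Predict from a PLS model
#'
#' @param object a `pls_model`.
#' @param newdata matrix (or vector for a single row) with the training
#'   columns.
#' @param n_components predict with the leading `n_components` only
#'   (defaults to all extracted components).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, n_components = NULL, ...) {
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  if (ncol(X) != length(object$xbar))
    stop("newdata has ", ncol(X), " columns; model expects ",
         length(object$xbar))
  if (!is.null(colnames(X)) && !is.null(object$colnames) &&
      !identical(colnames(X), object$colnames))
    stop("newdata column names do not match the model's descriptors")
  k <- if (is.null(n_components)) object$n_components
       else min(n_components, object$n_components)
  if (k == 0L) return(rep(object$ybar, nrow(X)))
  b <- pls_coef(object$W, object$P, object$Q, k)
  drop(sweep(X, 2, object$xbar) %*% b) + object$ybar
}

#' Leave-one-out cross-validation curve
#'
#' For each held-out compound the model is refit on the remainder and the
#' hold-out predicted, at every component count up to `max_components`.
#' `q2 = 1 - PRESS / SS_tot`, with `SS_tot` taken about the training-fold
#' means (each fold's own mean of the retained responses); a whole-set-mean
#' convention is available via `ss_tot`.
#' `SEP = sqrt(PRESS / (N - n - 1))`.
#'
#' @inheritParams fit_pls
#' @param max_components largest component count to evaluate.
#' @param ss_tot `"fold_mean"` (default) or `"whole_mean"`.
#' @return data frame `n_components, press, q2, sep`.
#' @export
loo_crossvalidate <- function(X, y, max_components = 10L,
                              ss_tot = c("fold_mean", "whole_mean")) {
  X <- as.matrix(X)
  ss_tot <- match.arg(ss_tot)
  N <- nrow(X)
  if (N < 3L) stop("leave-one-out needs at least 3 rows")
  A <- min(max_components, N - 2L, ncol(X))
  pred <- matrix(NA_real_, N, A)
  ref <- numeric(N)
  for (i in seq_len(N)) {
    # clipping short of A components in a fold is routine near full rank;
    # the fold prediction then reuses the largest extractable model
    fit <- suppressWarnings(fit_pls(X[-i, , drop = FALSE], y[-i], A))
    for (k in seq_len(A))
      pred[i, k] <- predict(fit, X[i, ], n_components = min(k, max(fit$n_components, 1L)))
    ref[i] <- mean(y[-i])
  }
  sst <- if (ss_tot == "fold_mean") sum((y - ref)^2) else sum((y - mean(y))^2)
  press <- colSums((y - pred)^2)
  data.frame(
    n_components = seq_len(A),
    press = press,
    q2 = 1 - press / sst,
    sep = sqrt(press / (N - seq_len(A) - 1))
  )
}

#' Choose the number of PLS components from a q2 curve
#'
#' Default policy: the component count maximizing q2, ties broken toward
#' the smaller count.  The parsimony policy takes the smallest count whose
#' q2 is within `tol` of the maximum.
#'
#' @param curve data frame from [loo_crossvalidate()].
#' @param policy `"max"` or `"parsimony"`.
#' @param tol q2 tolerance for the parsimony policy.
#' @param cap upper bound on the selected count.
#' @return selected component count (integer).
#' @export
select_components <- function(curve, policy = c("max", "parsimony"),
                              tol = 0.05, cap = 10L) {
  policy <- match.arg(policy)
  if (nrow(curve) == 0L) stop("empty q2 curve")
  curve <- curve[curve$n_components <= cap, , drop = FALSE]
  best <- max(curve$q2)
  n <- if (policy == "max")
    curve$n_components[which.max(curve$q2)]
  else
    min(curve$n_components[curve$q2 >= best - tol])
  as.integer(n)
}

#' Training-fit statistics: r2, SEE, F
#'
#' `r2 = 1 - SS_res / SS_tot`; `SEE = sqrt(SS_res / (N - n - 1))`;
#' `F = (SS_reg / n) / (SS_res / (N - n - 1))`, with `n` the number of
#' latent components (SYBYL degrees-of-freedom convention).
#'
#' @param model fitted `pls_model`.
#' @param X training design matrix.
#' @param y training response.
#' @return list `r2, see, f_value, n_components`.
#' @export
fit_statistics <- function(model, X, y) {
  n <- model$n_components
  N <- length(y)
  if (N <= n + 1L) stop("not enough degrees of freedom: N <= n + 1")
  yhat <- predict(model, X)
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  ss_reg <- ss_tot - ss_res
  list(
    r2 = 1 - ss_res / ss_tot,
    see = sqrt(ss_res / (N - n - 1)),
    f_value = if (n >= 1) (ss_reg / n) / (ss_res / (N - n - 1)) else NA_real_,
    n_components = n
  )
}

#' External predictivity: Q2_ext and r2_pred
#'
#' `Q2_ext = 1 - sum((y_i - yhat_i)^2) / sum((y_i - ybar_train)^2)`, the
#' reference sum taken about the *training* response mean, and `r2_pred`
#' the squared Pearson correlation between observed and predicted test
#' values.
#'
#' @param y_obs observed test responses (at least 2).
#' @param y_pred predicted test responses.
#' @param ybar_train mean response of the training set.
#' @return list `q2_ext, r2_pred, sep` where `sep` is the root mean square
#'   error of prediction on the test set.
#' @export
external_q2 <- function(y_obs, y_pred, ybar_train) {
  if (length(y_obs) < 2L) stop("need at least 2 test compounds")
  denom <- sum((y_obs - ybar_train)^2)
  if (denom < 1e-15)
    stop("test responses have no variance about the training mean")
  r2_pred <- if (stats::sd(y_obs) > 0 && stats::sd(y_pred) > 0)
    stats::cor(y_obs, y_pred)^2
  else NA_real_  # undefined for constant observed or predicted values
  list(
    q2_ext = 1 - sum((y_obs - y_pred)^2) / denom,
    r2_pred = r2_pred,
    sep = sqrt(mean((y_obs - y_pred)^2))
  )
}

partial_scramble <- function(y, frac) {
  n <- length(y)
  k <- round(frac * n)
  if (k < 2L) return(y)
  idx <- sample.int(n, k)
  y[idx] <- y[sample(idx)]
  y
}

#' Progressive y-scrambling stability analysis
#'
#' The response is partially scrambled over a ladder of perturbation
#' strengths (0 = untouched to 1 = fully permuted); at each draw the
#' squared correlation between true and perturbed responses (`r2_yy`) and
#' the leave-one-out `q2`/SDEP of the refit model are recorded.  A stable
#' model's q2 declines roughly linearly as r2_yy falls; the summary
#' statistics are the fitted slope `dq2_dr2yy` of q2 against r2_yy and
#' `csdep`, the cross-validated SDEP interpolated at the reference
#' correlation `r2_ref`.
#'
#' @inheritParams fit_pls
#' @param n_components components used for every refit.
#' @param reps scrambling draws per ladder level (>= 10).
#' @param levels number of perturbation strengths between 0 and 1.
#' @param r2_ref reference y-y' correlation for cSDEP (default 0.85).
#' @param seed integer seed; the whole procedure is reproducible.
#' @return list with the per-draw `table` (level, r2_yy, q2, sdep),
#'   `csdep`, `dq2_dr2yy`, and the unperturbed `q2_0`.
#' @export
progressive_scrambling <- function(X, y, n_components = 2L, reps = 10L,
                                   levels = 10L, r2_ref = 0.85, seed = 1L) {
  if (reps < 10L) stop("reps must be >= 10")
  X <- as.matrix(X)
  set.seed(seed)
  fracs <- seq(0, 1, length.out = levels)
  rows <- list()
  for (f in fracs) {
    nr <- if (f == 0) 1L else reps
    for (r in seq_len(nr)) {
      yp <- if (f == 0) y else partial_scramble(y, f)
      cv <- loo_crossvalidate(X, yp, n_components)
      k <- nrow(cv)
      rows[[length(rows) + 1L]] <- data.frame(
        level = f,
        r2_yy = stats::cor(y, yp)^2,
        q2 = cv$q2[k],
        sdep = cv$sep[k]
      )
    }
  }
  tab <- do.call(rbind, rows)
  slope <- stats::coef(stats::lm(q2 ~ r2_yy, data = tab))[["r2_yy"]]
  sfit <- stats::lm(sdep ~ r2_yy, data = tab)
  csdep <- unname(stats::predict(sfit, data.frame(r2_yy = r2_ref)))
  list(table = tab, csdep = csdep, dq2_dr2yy = slope, q2_0 = tab$q2[1])
}

#' Per-field contribution percentages
#'
#' Each descriptor block's share of the model, computed as the sum of
#' `|coefficient| * column standard deviation` over its columns,
#' normalized to 100%.
#'
#' @param model fitted `pls_model`.
#' @param table the `descriptor_table` the model was fit on (supplies the
#'   column-to-field mapping and the column standard deviations).
#' @return named numeric vector of percentages summing to 100.
#' @export
field_contributions <- function(model, table) {
  if (is.null(table$columns$field)) stop("descriptor table has no field labels")
  w <- abs(model$coefficients) * apply(table$X, 2, stats::sd)
  contrib <- tapply(w, table$columns$field, sum)
  out <- 100 * contrib / sum(contrib)
  out[order(names(out), decreasing = TRUE)]  # steric first
}

#' Seeded training/test split with the template in both roles
#'
#' Uniform random split of the compound ids.  The designated template
#' compound is guaranteed a training slot and is additionally carried in
#' the test list, mirroring the practice of keeping the target molecule in
#' both the training and the test set (its test copy is for evaluation
#' only and duplicates the training observation).
#'
#' @param ids compound identifiers.
#' @param train_size number of training compounds (default 22, the
#'   classical ~3:1 split of a 29-compound series).
#' @param seed integer seed.
#' @param template optional id forced into both sets.
#' @return list `train`, `test`, `seed` (a `split_spec`).
#' @export
make_split <- function(ids, train_size = 22L, seed = 1L, template = NULL) {
  n <- length(ids)
  if (train_size < 1L || train_size >= n)
    stop("train_size must be in [1, ", n - 1L, "]")
  set.seed(seed)
  train <- sample(ids, train_size)
  if (!is.null(template)) {
    if (!template %in% ids) stop("template '", template, "' not among ids")
    if (!template %in% train)
      train[sample.int(train_size, 1L)] <- template
  }
  test <- setdiff(ids, train)
  if (!is.null(template)) test <- union(test, template)
  structure(list(train = train, test = test, seed = seed),
            class = "split_spec")
}
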