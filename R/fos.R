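#' Logistic sigmoid
#'
#' `1 / (1 + exp(-x))`: monotone increasing, bounded in (0, 1). Applied to
#' max-normalized activation signals when building sigmoid basis functions.
#'
#' @param x Numeric.
#' @export
sigm <- function(x) 1 / (1 + exp(-x))

#' Candidate basis-function names
#'
#' @param kind `"dual"` for the two-muscle pool (bias + 13 functions of
#'   `H_BI` and `H_TR`), `"single"` for the one-grid pool (bias + 5
#'   functions of `H`).
#' @return Character vector of basis names in pool order (bias first, then
#'   fundamental, polynomial, square-root and sigmoid subsets).
#' @export
basis_names <- function(kind = c("dual", "single")) {
  kind <- match.arg(kind)
  if (kind == "dual") {
    c("bias",
      "H_BI", "H_TR", "H_BI*H_TR",
      "H_BI^2", "H_TR^2", "H_BI^3", "H_TR^3",
      "sqrt(H_BI)", "sqrt(H_TR)", "sqrt(H_BI*H_TR)",
      "sigm(H_BI)", "sigm(H_TR)", "sigm(H_BI)*sigm(H_TR)")
  } else {
    c("bias", "H", "H^2", "H^3", "sqrt(H)", "sigm(H)")
  }
}

# Evaluate one named basis function on activation signals. `h_tr` is unused
# for single-pool names.
eval_basis <- function(name, h_bi, h_tr = NULL) {
  switch(name,
    "bias" = rep(1, length(h_bi)),
    "H_BI" = h_bi,
    "H_TR" = h_tr,
    "H_BI*H_TR" = h_bi * h_tr,
    "H_BI^2" = h_bi^2,
    "H_TR^2" = h_tr^2,
    "H_BI^3" = h_bi^3,
    "H_TR^3" = h_tr^3,
    "sqrt(H_BI)" = sqrt(h_bi),
    "sqrt(H_TR)" = sqrt(h_tr),
    "sqrt(H_BI*H_TR)" = sqrt(h_bi * h_tr),
    "sigm(H_BI)" = sigm(h_bi),
    "sigm(H_TR)" = sigm(h_tr),
    "sigm(H_BI)*sigm(H_TR)" = sigm(h_bi) * sigm(h_tr),
    "H" = h_bi,
    "H^2" = h_bi^2,
    "H^3" = h_bi^3,
    "sqrt(H)" = sqrt(h_bi),
    "sigm(H)" = sigm(h_bi),
    stop_invalid(sprintf("unknown basis function name '%s'.", name))
  )
}

new_candidate_pool <- function(names, columns, kind) {
  structure(list(names = names, columns = columns, kind = kind),
            class = "candidate_pool")
}

check_activation_input <- function(h, name) {
  check_numeric_vector(h, name)
  if (any(h < 0)) {
    stop_invalid(sprintf("`%s` must be nonnegative (square-root candidates).", name))
  }
  invisible(h)
}

#' Build the two-muscle candidate basis pool
#'
#' Evaluates the full 14-function candidate pool on the agonist and
#' antagonist activation signals: an essential bias (constant 1) plus four
#' subsets — fundamental (`H_BI`, `H_TR`, `H_BI*H_TR`), polynomial
#' (squares and cubes of each signal), square-root (of each signal and of
#' the product), and sigmoid (of each signal and the product of sigmoids).
#'
#' @param h_bi,h_tr Nonnegative activation signals of equal length
#'   (biceps and triceps).
#' @return A `candidate_pool` with `names` and an evaluated samples x 14
#'   column matrix.
#' @examples
#' h <- seq(0, 1, length.out = 10)
#' length(candidate_pool(h, rev(h))$names)  # 14
#' @export
candidate_pool <- function(h_bi, h_tr) {
  check_activation_input(h_bi, "h_bi")
  check_activation_input(h_tr, "h_tr")
  check_same_length(h_bi, h_tr, "h_bi", "h_tr")
  nms <- basis_names("dual")
  cols <- vapply(nms, eval_basis, numeric(length(h_bi)),
                 h_bi = h_bi, h_tr = h_tr)
  new_candidate_pool(nms, cols, "dual")
}

#' Build the single-grid candidate basis pool
#'
#' Reduced pool used when only one electrode grid is available: bias plus
#' `H`, `H^2`, `H^3`, `sqrt(H)` and `sigm(H)` (6 functions).
#'
#' @param h Nonnegative activation signal.
#' @return A `candidate_pool` with 6 columns.
#' @export
candidate_pool_single <- function(h) {
  check_activation_input(h, "h")
  nms <- basis_names("single")
  cols <- vapply(nms, eval_basis, numeric(length(h)), h_bi = h)
  new_candidate_pool(nms, cols, "single")
}

#' @export
print.candidate_pool <- function(x, ...) {
  cat(sprintf("<candidate_pool> %s: %d functions x %d samples\n",
              x$kind, length(x$names), nrow(x$columns)))
  invisible(x)
}

#' Mean-square-error reduction of one candidate
#'
#' The quantity FOS maximizes at each greedy step: the candidate column is
#' orthogonalized (Gram-Schmidt) against the already-selected orthogonal
#' columns, and the reduction is `g^2 * mean(q^2)` with
#' `g = mean(q * residual) / mean(q^2)`. Returns 0 when the orthogonalized
#' energy falls below the collinearity tolerance (candidate lies in the
#' span of the selections).
#'
#' @param candidate Candidate basis column.
#' @param selected_q Matrix of already-selected orthogonal columns (or
#'   `NULL` / zero columns for the first step).
#' @param residual Current residual (or `y` itself; both give the same
#'   value because `q` is orthogonal to every selected column).
#' @param collinearity_tol Relative tolerance on `mean(q^2) / mean(p^2)`.
#' @return Scalar MSE reduction.
#' @export
mse_reduction <- function(candidate, selected_q = NULL, residual,
                          collinearity_tol = 1e-12) {
  check_same_length(candidate, residual, "candidate", "residual")
  q <- candidate
  if (!is.null(selected_q) && NCOL(selected_q) > 0) {
    selected_q <- as.matrix(selected_q)
    for (r in seq_len(ncol(selected_q))) {
      qr_ <- selected_q[, r]
      q <- q - (mean(q * qr_) / mean(qr_^2)) * qr_
    }
  }
  qq <- mean(q^2)
  if (qq < collinearity_tol * mean(candidate^2)) return(0)
  g <- mean(q * residual) / qq
  g^2 * qq
}

#' Fit a force model by fast orthogonal search
#'
#' Greedy forward selection over the candidate pool: at each step every
#' unselected candidate is orthogonalized against the already-selected
#' basis (modified Gram-Schmidt over stored columns), the candidate with
#' the largest mean-square-error reduction is added (ties broken by pool
#' order), and selection stops when `max_functions` are in the model or the
#' best remaining candidate would lower the training RMSD by less than
#' `rmsd_reduction_threshold` percentage points. Orthogonal-basis
#' coefficients `g_m` are converted to original-basis weights `a_m` by the
#' back-substitution recursion `a_m = sum_{i=m}^{M} g_i v_i`,
#' `v_m = 1`, `v_i = -sum_{r=m}^{i-1} alpha_{ir} v_r`, where `alpha_{ir}`
#' are the Gram-Schmidt projection coefficients. The resulting fit is
#' algebraically the least-squares projection of `y` onto the selected
#' columns. Candidates whose orthogonalized energy falls below the
#' collinearity tolerance are skipped and reported in `diagnostics`.
#'
#' @param y Measured force trace, normalized to unit maximum (see
#'   [normalize_to_max()]); RMSD is expressed in percent of that scale.
#' @param pool A [candidate_pool()] evaluated on the same samples.
#' @param max_functions Maximum model size M.
#' @param rmsd_reduction_threshold Stop when the best candidate's RMSD
#'   reduction (percentage points) falls below this.
#' @param collinearity_tol Relative orthogonalized-energy tolerance below
#'   which a candidate is treated as collinear and skipped.
#' @return A `fos_model`: `selected` names in selection order, coefficients
#'   `a` and `g`, Gram-Schmidt coefficients `alpha`, `training_rmsd_path`
#'   (percent RMSD after each added function), `fitted`, and `diagnostics`.
#' @examples
#' h <- seq(0, 1, length.out = 200)
#' y <- 0.5 * h + 0.1
#' m <- fos_fit(y, candidate_pool(h, h^2))
#' m$selected
#' @export
fos_fit <- function(y, pool, max_functions = 7, rmsd_reduction_threshold = 0.2,
                    collinearity_tol = 1e-12) {
  if (!inherits(pool, "candidate_pool")) stop_invalid("pool must be a candidate_pool.")
  P <- pool$columns
  n_pool <- ncol(P)
  if (n_pool == 0) stop_invalid("candidate pool is empty.")
  check_numeric_vector(y, "y")
  if (length(y) != nrow(P)) {
    stop_invalid("y and the pool columns must have equal lengths.")
  }
  max_functions <- min(max_functions, n_pool)
  nt <- length(y)

  Pperp <- P                       # candidates orthogonalized vs selections
  p_energy <- colMeans(P^2)
  alpha_cand <- matrix(0, n_pool, max_functions)  # coeff of q_r in p_j
  sel <- integer(0)
  Q <- matrix(0, nt, 0)
  qq <- numeric(0)
  g <- numeric(0)
  residual <- y
  mse <- mean(y^2)
  rmsd_path <- numeric(0)
  skipped <- character(0)
  termination <- "max_functions"

  while (length(sel) < max_functions) {
    avail <- setdiff(seq_len(n_pool), sel)
    q_energy <- colMeans(Pperp[, avail, drop = FALSE]^2)
    eligible <- q_energy >= collinearity_tol * p_energy[avail]
    if (!any(eligible)) {
      skipped <- union(skipped, pool$names[avail])
      termination <- "all_candidates_collinear"
      break
    }
    red <- rep(-Inf, length(avail))
    gs <- numeric(length(avail))
    for (i in seq_along(avail)) {
      if (!eligible[i]) next
      gs[i] <- mean(Pperp[, avail[i]] * residual) / q_energy[i]
      red[i] <- gs[i]^2 * q_energy[i]
    }
    best <- which.max(red)         # ties -> lowest pool index (pool order)
    mse_new <- max(mse - red[best], 0)
    if ((sqrt(mse) - sqrt(mse_new)) * 100 < rmsd_reduction_threshold) {
      termination <- "rmsd_reduction_below_threshold"
      break
    }
    j <- avail[best]
    q_new <- Pperp[, j]
    m_idx <- length(sel) + 1L
    sel <- c(sel, j)
    Q <- cbind(Q, q_new)
    qq <- c(qq, q_energy[best])
    g <- c(g, gs[best])
    residual <- residual - gs[best] * q_new
    mse <- mean(residual^2)
    rmsd_path <- c(rmsd_path, sqrt(mse) * 100)
    # orthogonalize the remaining candidates against the new q
    remaining <- setdiff(seq_len(n_pool), sel)
    if (length(remaining) > 0) {
      cj <- colMeans(Pperp[, remaining, drop = FALSE] * q_new) / qq[m_idx]
      Pperp[, remaining] <- Pperp[, remaining, drop = FALSE] -
        outer(q_new, cj)
      alpha_cand[remaining, m_idx] <- cj
    }
  }

  M <- length(sel)
  alpha <- matrix(0, M, M)
  if (M > 1) {
    for (i in 2:M) alpha[i, seq_len(i - 1)] <- alpha_cand[sel[i], seq_len(i - 1)]
  }
  a <- numeric(M)
  for (m in seq_len(M)) {
    v <- numeric(M)
    v[m] <- 1
    if (m < M) {
      for (i in (m + 1):M) {
        v[i] <- -sum(alpha[i, m:(i - 1)] * v[m:(i - 1)])
      }
    }
    a[m] <- sum(g[m:M] * v[m:M])
  }
  fitted <- if (M > 0) as.numeric(P[, sel, drop = FALSE] %*% a) else rep(0, nt)

  structure(
    list(selected = pool$names[sel], pool_kind = pool$kind,
         g = g, a = a, alpha = alpha,
         training_rmsd_path = rmsd_path,
         fitted = fitted, residual_mse = mse, n_samples = nt,
         max_functions = max_functions,
         rmsd_reduction_threshold = rmsd_reduction_threshold,
         diagnostics = list(termination = termination, skipped = skipped)),
    class = "fos_model"
  )
}

#' Predict force from a fitted FOS model
#'
#' Evaluates `sum_m a_m p_m(t)` over the selected basis functions on new
#' activation signals.
#'
#' @param model A fitted `fos_model`.
#' @param h_bi Activation signal (the only input for single-pool models).
#' @param h_tr Antagonist activation signal (dual-pool models).
#' @return Predicted force trace.
#' @export
fos_predict <- function(model, h_bi, h_tr = NULL) {
  if (!inherits(model, "fos_model") || is.null(model$selected)) {
    rlang::abort("model must be a fitted fos_model.", class = "fosemg_state_error")
  }
  if (model$pool_kind == "dual") {
    if (is.null(h_tr)) stop_invalid("dual-pool models require h_tr.")
    check_same_length(h_bi, h_tr, "h_bi", "h_tr")
  }
  if (length(model$a) == 0) return(rep(0, length(h_bi)))
  cols <- vapply(model$selected, eval_basis, numeric(length(h_bi)),
                 h_bi = h_bi, h_tr = h_tr)
  as.numeric(cols %*% model$a)
}

#' @export
predict.fos_model <- function(object, h_bi, h_tr = NULL, ...) {
  fos_predict(object, h_bi, h_tr)
}

#' @export
print.fos_model <- function(x, ...) {
  cat(sprintf("<fos_model> %s pool, %d basis functions, training RMSD %.4g%%\n",
              x$pool_kind, length(x$selected),
              if (length(x$training_rmsd_path)) utils::tail(x$training_rmsd_path, 1) else NaN))
  if (length(x$selected)) {
    print(tibble::tibble(term = x$selected, a = x$a))
  }
  invisible(x)
}

#' Tidy a FOS model
#'
#' One row per selected basis function, in selection order, with the
#' original-basis coefficient `a`, the orthogonal-basis coefficient `g`,
#' and the training RMSD (percent) after that function entered the model.
#'
#' @param x A `fos_model`.
#' @param ... Unused.
#' @return A tibble with columns `step`, `term`, `estimate`, `g`,
#'   `rmsd_after`.
#' @export
tidy.fos_model <- function(x, ...) {
  tibble::tibble(step = seq_along(x$selected), term = x$selected,
                 estimate = x$a, g = x$g, rmsd_after = x$training_rmsd_path)
}

#' Glance at a FOS model
#'
#' @param x A `fos_model`.
#' @param ... Unused.
#' @return A one-row tibble: number of terms, final training RMSD (percent),
#'   sample count and termination reason.
#' @export
glance.fos_model <- function(x, ...) {
  tibble::tibble(
    n_terms = length(x$selected),
    training_rmsd = if (length(x$training_rmsd_path))
      utils::tail(x$training_rmsd_path, 1) else NA_real_,
    n_samples = x$n_samples,
    termination = x$diagnostics$termination
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
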