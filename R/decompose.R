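# Phase decomposition: express a heterogeneous order distribution as a
# non-negative, sum-to-one mixture of reference (gel / Lo / Ld)
# distributions by constrained least squares over the concatenated
# per-carbon histograms.

#' Fit a simplex-constrained mixture of reference distributions
#'
#' Minimizes `|| target - sum_i f_i ref_i ||^2` over the concatenated
#' per-carbon histogram cells, subject to `f_i >= 0` and `sum f_i = 1`
#' (enforced exactly). The solver enumerates active sets of the KKT system,
#' which is exact for the small component counts used here; degenerate
#' (collinear) reference sets resolve to the minimum-norm fraction vector
#' via the pseudo-inverse.
#'
#' @param target An `order_distribution`.
#' @param refs List of reference `order_distribution`s (>= 2), sharing the
#'   target's carbon list and bin edges. Names become component labels.
#' @param labels Component labels (default `names(refs)` or `ref1..refK`).
#' @return A `mixture_fit`: fractions, fitted distribution, L1-relative
#'   error (%), and the least-squares objective. Has [tidy()] and
#'   [glance()] methods.
#' @export
fit_mixture <- function(target, refs, labels = NULL) {
  stopifnot(inherits(target, "order_distribution"))
  if (length(refs) < 2L) stop("need at least 2 reference distributions")
  for (r in refs) {
    if (!inherits(r, "order_distribution"))
      stop("refs must be order_distribution objects")
    if (!identical(r$carbons, target$carbons) ||
        length(r$breaks) != length(target$breaks) ||
        max(abs(r$breaks - target$breaks)) > 1e-9)
      stop("alignment error: reference and target must share carbon list ",
           "and bin edges")
  }
  if (is.null(labels))
    labels <- names(refs) %||% paste0("ref", seq_along(refs))
  if (is.null(names(refs)) && !is.null(labels)) names(refs) <- labels
  b <- as.vector(target$mass)
  if (all(b == 0)) stop("degenerate error: all-zero target distribution")
  A <- vapply(refs, function(r) as.vector(r$mass), numeric(length(b)))
  f <- simplex_lsq(A, b)
  fitted_mass <- matrix(as.vector(A %*% f), nrow = nrow(target$mass))
  # renormalize rows against accumulated rounding only (sums are ~1 already)
  fitted <- new_order_distribution(target$carbons, target$breaks,
                                   fitted_mass / rowSums(fitted_mass),
                                   provenance = "mixture fit")
  err <- fit_error(target, fitted)
  structure(list(labels = labels,
                 fractions = stats::setNames(f, labels),
                 fitted = fitted, error_pct = err,
                 objective = sum((A %*% f - b)^2), target = target),
            class = "mixture_fit")
}

# Exact solver for min ||A f - b||^2 s.t. f >= 0, sum f = 1, by enumeration
# of active (zero) sets; ginv handles rank-deficient KKT systems, giving
# the minimum-norm solution among ties.
simplex_lsq <- function(A, b) {
  K <- ncol(A)
  if (K > 12L) stop("active-set enumeration supports at most 12 components")
  best <- NULL; best_obj <- Inf; best_norm <- Inf
  for (mask in seq_len(2^K) - 1L) {
    S <- which(bitwAnd(mask, 2^(seq_len(K) - 1L)) > 0L)
    if (!length(S)) next
    As <- A[, S, drop = FALSE]
    k <- length(S)
    kkt <- rbind(cbind(2 * crossprod(As), rep(1, k)),
                 c(rep(1, k), 0))
    rhs <- c(2 * crossprod(As, b), 1)
    sol <- tryCatch(solve(kkt, rhs),
                    error = function(e) MASS::ginv(kkt) %*% rhs)
    fs <- as.vector(sol)[seq_len(k)]
    if (any(fs < -1e-10)) next
    fs <- pmax(fs, 0); fs <- fs / sum(fs)
    f <- numeric(K); f[S] <- fs
    obj <- sum((A %*% f - b)^2)
    nrm <- sum(f^2)
    if (obj < best_obj - 1e-12 ||
        (obj < best_obj + 1e-12 && nrm < best_norm - 1e-12)) {
      best <- f; best_obj <- obj; best_norm <- nrm
    }
  }
  if (is.null(best)) stop("mixture fit failed: no feasible active set")
  best
}

#' L1-relative reproduction error of a mixture fit, in percent
#'
#' `100 * sum |target - fitted| / sum target` over all carbon-bin cells.
#'
#' @param target An `order_distribution`.
#' @param fit A `mixture_fit`, an `order_distribution`, or a mass matrix on
#'   the target's grid (not renormalized here, so scaled inputs are
#'   compared as-is).
#' @return Error in percent (>= 0).
#' @export
fit_error <- function(target, fit) {
  fm <- if (inherits(fit, "mixture_fit")) fit$fitted$mass
        else if (inherits(fit, "order_distribution")) fit$mass
        else fit
  tm <- target$mass
  if (!all(dim(fm) == dim(tm)))
    stop("alignment error: fitted and target grids differ")
  100 * sum(abs(tm - fm)) / sum(tm)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("<mixture_fit> ", paste(sprintf("%s = %.1f%%", x$labels,
                                      100 * x$fractions), collapse = ", "),
      "; reproduction error ", sprintf("%.2f%%", x$error_pct), "\n", sep = "")
  invisible(x)
}

#' Tidy a mixture fit into one row per component
#' @param x A `mixture_fit`.
#' @param ... Unused.
#' @return Tibble with `component`, `fraction`.
#' @export
tidy.mixture_fit <- function(x, ...) {
  tibble::tibble(component = x$labels, fraction = unname(x$fractions))
}

#' One-row summary of a mixture fit
#' @param x A `mixture_fit`.
#' @param ... Unused.
#' @return Tibble with `error_pct`, `objective`, `n_components`.
#' @export
glance.mixture_fit <- function(x, ...) {
  tibble::tibble(error_pct = x$error_pct, objective = x$objective,
                 n_components = length(x$fractions))
}
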