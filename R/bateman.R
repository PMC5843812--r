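# Closed-form branching Bateman kinetics for the Bi-213 chain.
#
# Po-213 (T1/2 = 4.2 us) makes the textbook Bateman coefficients
# catastrophically ill-conditioned (lambda_Po / lambda_Bi ~ 6.5e8), so any
# nuclide whose decay constant exceeds `fast_lambda` is treated as a
# transient in secular equilibrium with its parent:
#   A_fast(t) = b * A_parent(t) * (1 - exp(-lambda_fast * t)),
# and acts as a pass-through when feeding its own daughters. The relative
# error of this contraction is O(lambda_parent / lambda_fast) < 1e-8 here.

# Per-nuclide feeding paths from the chain parent: for each nuclide, the
# list of (lambda vector along the path, product of branch fractions),
# with fast members contracted out.
chain_paths <- function(chain, fast_lambda = 1e2) {
  nucs <- chain$nuclides
  parent <- names(nucs)[1L]
  paths <- stats::setNames(vector("list", length(nucs)), names(nucs))
  walk <- function(name, lambdas, frac) {
    n <- nucs[[name]]
    lam <- n$decay_constant_per_s
    fast <- lam > fast_lambda
    if (!fast) lambdas <- c(lambdas, stats::setNames(lam, name))
    paths[[name]] <<- c(paths[[name]],
                        list(list(lambdas = lambdas, frac = frac, fast = fast,
                                  lambda_self = lam)))
    for (i in seq_len(nrow(n$branches))) {
      d <- n$branches$daughter[i]
      if (d %in% names(nucs))
        walk(d, lambdas, frac * n$branches$fraction[i])
    }
  }
  walk(parent, numeric(0), 1)
  paths
}

# Bateman sum for a path of distinct decay constants, evaluated as
# activity of the terminal member per unit initial parent activity.
# lambdas: decay constants along the (contracted) path, terminal last.
bateman_terms <- function(lambdas) {
  k <- length(lambdas)
  coef <- vapply(seq_len(k), function(i) {
    denom <- prod(lambdas[-i] - lambdas[i])
    if (k == 1) 1 else prod(lambdas[-k]) / denom
  }, numeric(1))
  # activity of terminal member per unit initial parent *activity*:
  # A_k(t)/A_1(0) = (lambda_k/lambda_1) * prod(lambda_{1..k-1}) *
  #                 sum_i coef_i exp(-lambda_i t)  -- folded into coef here
  coef * lambdas[k] / lambdas[1]
}

#' Chain activities over a time grid
#'
#' Closed-form branching Bateman solution for a pure-parent start: the first
#' nuclide of the chain holds all activity at t = 0 and every daughter is
#' zero. Activities are in the same unit as `A0_MBq`.
#'
#' @param chain a `decay_chain` (see [bi213_chain()]).
#' @param A0_MBq initial parent activity (MBq), > 0.
#' @param time_grid_s numeric vector of times in seconds, sorted increasing,
#'   starting at 0.
#' @return an `activity_curve`: list with `time_s` and matrix
#'   `activity_MBq` (times x nuclides), plus `A0_MBq`.
#' @export
chain_activities <- function(chain, A0_MBq, time_grid_s) {
  if (!is.numeric(A0_MBq) || length(A0_MBq) != 1 || A0_MBq < 0)
    stop("A0_MBq must be a single non-negative number")
  if (is.unsorted(time_grid_s, strictly = FALSE) || time_grid_s[1] != 0)
    stop("time_grid_s must be sorted increasing and start at 0")

  paths <- chain_paths(chain)
  act <- matrix(0, nrow = length(time_grid_s), ncol = length(chain$nuclides),
                dimnames = list(NULL, names(chain$nuclides)))
  for (nm in names(paths)) {
    for (p in paths[[nm]]) {
      if (p$fast) {
        # equilibrium transient: b * A_parent(t) * (1 - exp(-lambda_self t))
        lam <- p$lambdas
        k <- length(lam)
        a_par <- if (k == 0) rep(1, length(time_grid_s)) else {
          cf <- bateman_terms(lam)
          as.vector(exp(-outer(time_grid_s, lam)) %*% cf)
        }
        act[, nm] <- act[, nm] + A0_MBq * p$frac * a_par *
          (1 - exp(-p$lambda_self * time_grid_s))
      } else {
        cf <- bateman_terms(p$lambdas)
        act[, nm] <- act[, nm] +
          A0_MBq * p$frac * as.vector(exp(-outer(time_grid_s, p$lambdas)) %*% cf)
      }
    }
  }
  act[act < 0 & act > -1e-12 * A0_MBq] <- 0   # clip roundoff
  structure(list(time_s = time_grid_s, activity_MBq = act, A0_MBq = A0_MBq),
            class = "activity_curve")
}

#' Time-integrated activities over [0, T]
#'
#' Analytic integral of every Bateman exponential term; no quadrature.
#' Units are MBq.s (equivalently, millions of decays).
#'
#' @inheritParams chain_activities
#' @param T_s horizon in seconds (scalar or vector), > 0 (0 allowed and
#'   yields 0).
#' @return matrix (length(T_s) x nuclides) of integrated activities in MBq.s.
#' @export
integrated_activities <- function(chain, A0_MBq, T_s) {
  if (any(T_s < 0)) stop("T_s must be >= 0")
  paths <- chain_paths(chain)
  out <- matrix(0, nrow = length(T_s), ncol = length(chain$nuclides),
                dimnames = list(NULL, names(chain$nuclides)))
  int_exp <- function(lam, T) (1 - exp(-lam * T)) / lam
  for (nm in names(paths)) {
    for (p in paths[[nm]]) {
      if (p$fast) {
        lam <- p$lambdas
        ls <- p$lambda_self
        if (length(lam) == 0) {
          stop("chain parent may not be a fast transient")
        } else {
          cf <- bateman_terms(lam)
          # integral of b * A_par(t) (1 - exp(-ls t))
          #   = b * [ sum_i cf_i int_exp(lam_i) - sum_i cf_i int_exp(lam_i+ls) ]
          term <- vapply(seq_along(T_s), function(j) {
            sum(cf * (int_exp(lam, T_s[j]) - int_exp(lam + ls, T_s[j])))
          }, numeric(1))
          out[, nm] <- out[, nm] + A0_MBq * p$frac * term
        }
      } else {
        cf <- bateman_terms(p$lambdas)
        term <- vapply(seq_along(T_s), function(j) {
          sum(cf * int_exp(p$lambdas, T_s[j]))
        }, numeric(1))
        out[, nm] <- out[, nm] + A0_MBq * p$frac * term
      }
    }
  }
  out
}

#' Default time grid for activity and dose curves
#'
#' Logarithmic from 1 ms to 60 s (resolving Po-213 ingrowth and Tl-209
#' early ingrowth), then linear to the horizon; 600 points, starting at 0.
#'
#' @param horizon_s end of the grid, default 120 min.
#' @param n total number of points.
#' @return numeric vector of times (s).
#' @export
default_time_grid <- function(horizon_s = 7200, n = 600) {
  n_log <- round(n / 3)
  c(0, exp(seq(log(1e-3), log(60), length.out = n_log)),
    seq(60, horizon_s, length.out = n - n_log - 1)[-1])
}
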