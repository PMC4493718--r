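#' Solve a small dense linear program
#'
#' Thin wrapper around the two-phase simplex method (`boot::simplex`) that
#' accepts general variable bounds and signed right-hand sides. Minimizes (or
#' maximizes) `obj %*% x` subject to `A x <= b`, `Aeq x = beq` and
#' `lb <= x <= ub`. Lower bounds must be finite (the problem is shifted to
#' the non-negative orthant internally); upper bounds may be infinite.
#'
#' This is the generic subroutine behind the two-cell oracle, the Chebyshev
#' interior-point search, polytope coordinate bounds and the
#' linear-programming maxima that the Boltzmann-biased sampler is compared
#' against.
#'
#' @param obj Objective coefficient vector.
#' @param A,b Inequality constraints `A x <= b` (may be `NULL`).
#' @param Aeq,beq Equality constraints (may be `NULL`).
#' @param lb,ub Variable bounds; scalars are recycled. Infinite lower bounds
#'   are handled by splitting the variable into positive and negative parts.
#' @param maximize Maximize instead of minimize.
#' @return A list with `x` (solution), `value` (objective at `x`) and
#'   `status` (`"optimal"`, `"infeasible"` or `"unbounded"`).
#' @examples
#' solve_lp(c(-1, -2), A = rbind(c(1, 1)), b = 1, lb = 0, ub = Inf)
#' @export
solve_lp <- function(obj, A = NULL, b = NULL, Aeq = NULL, beq = NULL,
                     lb = 0, ub = Inf, maximize = FALSE) {
  n <- length(obj)
  lb <- rep_len(lb, n); ub <- rep_len(ub, n)
  if (any(ub < lb)) return(list(x = rep(NA_real_, n), value = NA_real_,
                                status = "infeasible"))
  split <- which(!is.finite(lb))
  if (length(split)) {
    # x_j = x_j^+ - x_j^-: append mirrored columns for the split variables;
    # their own upper bounds become explicit rows on the difference
    fin_ub <- split[is.finite(ub[split])]
    if (length(fin_ub)) {
      Ub <- matrix(0, length(fin_ub), n)
      Ub[cbind(seq_along(fin_ub), fin_ub)] <- 1
      A <- rbind(A, Ub); b <- c(b, ub[fin_ub])
      ub[fin_ub] <- Inf
    }
    ext <- function(M) if (is.null(M)) NULL else
      cbind(matrix(M, ncol = n), -matrix(M, ncol = n)[, split, drop = FALSE])
    lb2 <- lb; lb2[split] <- 0
    res <- solve_lp(c(obj, -obj[split]), A = ext(A), b = b,
                    Aeq = ext(Aeq), beq = beq,
                    lb = c(lb2, numeric(length(split))),
                    ub = c(ub, rep(Inf, length(split))),
                    maximize = maximize)
    if (res$status == "optimal") {
      x <- res$x[seq_len(n)]
      x[split] <- x[split] - res$x[n + seq_along(split)]
      return(list(x = x, value = sum(obj * x), status = "optimal"))
    }
    return(list(x = rep(NA_real_, n), value = NA_real_, status = res$status))
  }
  if (!is.null(A)) {
    A <- matrix(A, ncol = n)
    stopifnot(length(b) == nrow(A))
  }
  # fold finite upper bounds into inequality rows
  fin <- which(is.finite(ub))
  if (length(fin)) {
    Ub <- matrix(0, length(fin), n)
    Ub[cbind(seq_along(fin), fin)] <- 1
    A <- rbind(A, Ub); b <- c(b, ub[fin])
  }
  # shift x = y + lb, y >= 0
  if (!is.null(A)) b <- b - as.vector(A %*% lb)
  if (!is.null(Aeq)) {
    Aeq <- matrix(Aeq, ncol = n)
    beq <- beq - as.vector(Aeq %*% lb)
  }
  # boot::simplex wants non-negative rhs: flip rows as needed
  A1 <- NULL; b1 <- NULL; A2 <- NULL; b2 <- NULL
  if (!is.null(A)) {
    neg <- b < 0
    if (any(!neg)) { A1 <- A[!neg, , drop = FALSE]; b1 <- b[!neg] }
    if (any(neg)) { A2 <- -A[neg, , drop = FALSE]; b2 <- -b[neg] }
  }
  A3 <- NULL; b3 <- NULL
  if (!is.null(Aeq)) {
    sgn <- ifelse(beq < 0, -1, 1)
    A3 <- Aeq * sgn; b3 <- beq * sgn
  }
  res <- boot::simplex(a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                       A3 = A3, b3 = b3, maxi = maximize)
  status <- switch(as.character(res$solved),
                   "1" = "optimal", "0" = "unbounded", "-1" = "infeasible",
                   "unknown")
  x <- if (status == "optimal") as.numeric(res$soln) + lb else rep(NA_real_, n)
  list(x = x, value = if (status == "optimal") sum(obj * x) else NA_real_,
       status = status)
}
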