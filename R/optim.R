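#' @name owlqn
#' @title Quasi-Newton optimizer with orthant-wise L1 handling
#'
#' @description Limited-memory BFGS minimizer for objectives of the form
#' `f(w) + l1 * sum(|w|)` with `f` smooth. When `l1 > 0` the orthant-wise
#' variant (OWL-QN) is used: the search direction is built from the
#' pseudo-gradient of the L1 term, constrained to the current orthant, and
#' iterates are projected so coordinates never cross zero within a step.
#' With `l1 = 0` it reduces to plain L-BFGS with Armijo backtracking. The
#' routine is fully deterministic.
#'
#' @param par Numeric start vector.
#' @param fn_gr Function of `w` returning `list(f = <smooth value>,
#'   g = <smooth gradient>)`.
#' @param l1 Non-negative L1 penalty weight.
#' @param max_iter Maximum iterations.
#' @param tol Convergence tolerance on the max-norm of the
#'   (pseudo-)gradient.
#' @param m Number of curvature pairs kept.
#' @return List with `par`, `value` (penalized objective), `converged`,
#'   `iterations`, and `trace` (objective value after each accepted step).
#' @keywords internal
owlqn <- function(par, fn_gr, l1 = 0, max_iter = 100L, tol = 1e-5,
                  m = 10L) {
  w <- par
  ev <- fn_gr(w)
  f <- ev$f; g <- ev$g
  Fw <- f + l1 * sum(abs(w))
  S <- list(); Y <- list(); rho <- numeric(0)
  trace <- numeric(0)
  converged <- FALSE
  iterations <- 0L

  pseudo_grad <- function(w, g) {
    if (l1 == 0) return(g)
    pg <- numeric(length(w))
    pos <- w > 0; neg <- w < 0; z <- !pos & !neg
    pg[pos] <- g[pos] + l1
    pg[neg] <- g[neg] - l1
    gp <- g[z] + l1; gm <- g[z] - l1
    pz <- numeric(sum(z))
    pz[gp < 0] <- gp[gp < 0]
    pz[gm > 0] <- gm[gm > 0]
    pg[z] <- pz
    pg
  }

  two_loop <- function(q) {
    k <- length(S)
    if (k == 0L) return(q)
    a <- numeric(k)
    for (i in k:1) {
      a[i] <- rho[i] * sum(S[[i]] * q)
      q <- q - a[i] * Y[[i]]
    }
    gamma <- sum(S[[k]] * Y[[k]]) / sum(Y[[k]] * Y[[k]])
    q <- gamma * q
    for (i in 1:k) {
      b <- rho[i] * sum(Y[[i]] * q)
      q <- q + (a[i] - b) * S[[i]]
    }
    q
  }

  for (it in seq_len(max_iter)) {
    pg <- pseudo_grad(w, g)
    if (max(abs(pg)) < tol) { converged <- TRUE; break }
    d <- -two_loop(pg)
    if (l1 > 0) d[d * pg > 0] <- 0
    dd <- sum(pg * d)
    if (!is.finite(dd) || dd >= 0) {
      d <- -pg
      dd <- sum(pg * d)
      if (dd >= 0) { converged <- TRUE; break }  # pg == 0
    }
    xi <- ifelse(w != 0, sign(w), -sign(pg))
    alpha <- if (length(S) == 0L) min(1, 1 / sum(abs(pg))) else 1
    accepted <- FALSE
    for (ls in 1:50) {
      wn <- w + alpha * d
      if (l1 > 0) wn[wn * xi < 0] <- 0
      evn <- fn_gr(wn)
      Fn <- evn$f + l1 * sum(abs(wn))
      if (is.finite(Fn) && Fn <= Fw + 1e-4 * sum(pg * (wn - w))) {
        accepted <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    if (!accepted) break
    s <- wn - w
    y <- evn$g - g
    sy <- sum(s * y)
    if (is.finite(sy) && sy > 1e-10) {
      S[[length(S) + 1L]] <- s
      Y[[length(Y) + 1L]] <- y
      rho <- c(rho, 1 / sy)
      if (length(S) > m) {
        S <- S[-1L]; Y <- Y[-1L]; rho <- rho[-1L]
      }
    }
    w <- wn; f <- evn$f; g <- evn$g; Fw <- Fn
    trace <- c(trace, Fw)
    iterations <- it
  }
  list(par = w, value = Fw, converged = converged,
       iterations = iterations, trace = trace)
}
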