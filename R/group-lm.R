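# Levenberg-Marquardt for globally fitted groups: a few shared parameters
# plus an independent parameter block per group member.  The Jacobian is
# block-sparse (a member's residuals depend only on the shared parameters and
# its own block), so finite differences on a block parameter re-evaluate that
# member only -- this is what makes 28-profile global fits cheap.

# evaluate a residual expression, mapping invalid parameter combinations
# (rejected by the model constructors or the propagator) to a large penalty
safe_resid <- function(expr, n) {
  r <- tryCatch(expr, error = function(e) NULL)
  if (is.null(r) || length(r) != n || any(!is.finite(r))) rep(1e6, n) else r
}

group_residuals <- function(shared, blocks, resid_fn) {
  unlist(lapply(seq_along(blocks), function(i) resid_fn(shared, blocks[[i]], i)),
         use.names = FALSE)
}

#' @keywords internal
group_lm <- function(shared0, blocks0, resid_fn,
                     max_iter = 100L, ftol = 1e-10, verbose = FALSE) {
  shared <- shared0
  blocks <- blocks0
  ns <- length(shared)
  nb <- lengths(blocks)
  m <- length(blocks)
  npar <- ns + sum(nb)
  blk_off <- ns + c(0L, cumsum(nb))[seq_len(m)]  # 0-based offsets per block

  res_list <- lapply(seq_len(m), function(i) resid_fn(shared, blocks[[i]], i))
  nres <- lengths(res_list)
  res_off <- c(0L, cumsum(nres))[seq_len(m)]
  r <- unlist(res_list, use.names = FALSE)
  ssr <- sum(r^2)

  jacobian <- function(shared, blocks, res_list, r) {
    J <- matrix(0, length(r), npar)
    for (j in seq_len(ns)) {
      h <- 1e-6 * (abs(shared[j]) + 1e-3)
      sh <- shared; sh[j] <- sh[j] + h
      rp <- group_residuals(sh, blocks, resid_fn)
      J[, j] <- (rp - r) / h
    }
    for (i in seq_len(m)) {
      rows <- res_off[i] + seq_len(nres[i])
      for (j in seq_len(nb[i])) {
        h <- 1e-6 * (abs(blocks[[i]][j]) + 1e-3)
        bl <- blocks[[i]]; bl[j] <- bl[j] + h
        rp <- resid_fn(shared, bl, i)
        J[rows, blk_off[i] + j] <- (rp - res_list[[i]]) / h
      }
    }
    J
  }

  lambda <- 1e-3
  converged <- FALSE
  iter <- 0L
  J <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    J <- jacobian(shared, blocks, res_list, r)
    g <- crossprod(J, r)
    A <- crossprod(J)
    accepted <- FALSE
    for (try in 1:12) {
      Ad <- A + lambda * diag(pmax(diag(A), 1e-12), npar)
      step <- tryCatch(-solve(Ad, g), error = function(e) NULL)
      if (is.null(step)) { lambda <- lambda * 10; next }
      sh_new <- shared + step[seq_len(ns)]
      bl_new <- blocks
      for (i in seq_len(m))
        bl_new[[i]] <- blocks[[i]] + step[blk_off[i] + seq_len(nb[i])]
      rl_new <- lapply(seq_len(m), function(i) resid_fn(sh_new, bl_new[[i]], i))
      r_new <- unlist(rl_new, use.names = FALSE)
      ssr_new <- sum(r_new^2)
      if (is.finite(ssr_new) && ssr_new < ssr) {
        rel <- (ssr - ssr_new) / max(ssr, 1e-300)
        shared <- sh_new; blocks <- bl_new
        res_list <- rl_new; r <- r_new
        ssr_old <- ssr; ssr <- ssr_new
        lambda <- max(lambda / 3, 1e-12)
        accepted <- TRUE
        if (rel < ftol) converged <- TRUE
        break
      }
      lambda <- lambda * 5
    }
    if (!accepted) { converged <- TRUE; break }
    if (converged) break
    if (verbose) message(sprintf("iter %d ssr %.6g lambda %.2g", iter, ssr, lambda))
  }

  # covariance of the (weighted) estimates at the solution
  if (is.null(J)) J <- jacobian(shared, blocks, res_list, r)
  dof <- max(length(r) - npar, 1L)
  s2 <- ssr / dof
  A <- crossprod(J)
  cov <- tryCatch(solve(A) * s2, error = function(e)
    matrix(NA_real_, npar, npar))
  se <- sqrt(pmax(diag(cov), 0))
  dn <- sqrt(diag(cov))
  cor <- cov / outer(dn, dn)

  list(shared = shared, blocks = blocks, ssr = ssr,
       chi2_reduced = ssr / dof, dof = dof,
       se_shared = se[seq_len(ns)],
       se_blocks = lapply(seq_len(m), function(i) se[blk_off[i] + seq_len(nb[i])]),
       cov = cov, cor = cor, n_shared = ns,
       iterations = iter, converged = converged)
}
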