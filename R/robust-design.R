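## Robust-design likelihood machinery.
##
## The joint log-likelihood of a fit factors into (a) Huggins conditional
## closed-capture likelihoods within each patch x primary session, carrying
## the information on p and c, and (b) an open-process likelihood on the
## collapsed (session-level) histories of each patch, carrying phi and
## lambda, with session-level detection p*_t = 1 - (1 - p_t)^K tied to the
## same p as the closed part.

#' Parameter structure of a robust-design model
#'
#' Apparent survival (phi, logit link) and population rate of change
#' (lambda, log link) can each be constant across patches, landscape
#' specific, or patch specific; capture (p) and recapture (c) rates are by
#' default additive in patch and primary session on the logit scale.
#'
#' @param phi,lambda One of `"constant"`, `"landscape"`, `"patch"`.
#' @param detection `"patch_session"` (additive patch + session effects,
#'   the standard structure) or `"constant"`.
#' @return An object of class `rd_structure`.
#' @export
rd_structure <- function(phi = "constant", lambda = "constant",
                         detection = "patch_session") {
  phi <- match.arg(phi, c("constant", "landscape", "patch"))
  lambda <- match.arg(lambda, c("constant", "landscape", "patch"))
  detection <- match.arg(detection, c("patch_session", "constant"))
  structure(list(phi = phi, lambda = lambda, detection = detection),
            class = "rd_structure")
}

#' @export
print.rd_structure <- function(x, ...) {
  cat(structure_label(x), "\n")
  invisible(x)
}

structure_label <- function(s) {
  abbr <- c(constant = ".", landscape = "ls", patch = "pa")
  det <- if (s$detection == "patch_session") "pa+t" else "."
  sprintf("phi(%s) lambda(%s) p(%s) c(%s)",
          abbr[[s$phi]], abbr[[s$lambda]], det, det)
}

#' The nine standard candidate structures
#'
#' All combinations of constant / landscape-specific / patch-specific phi
#' and lambda, always with additive patch + session detection, ordered as
#' conventionally tabled (I1 the null model through I9 the fully
#' patch-specific model).
#'
#' @return A named list of [rd_structure()] objects I1..I9.
#' @export
rd_structures <- function() {
  combos <- list(
    I1 = c("constant", "constant"),
    I2 = c("landscape", "landscape"),
    I3 = c("landscape", "constant"),
    I4 = c("constant", "landscape"),
    I5 = c("patch", "landscape"),
    I6 = c("landscape", "patch"),
    I7 = c("patch", "constant"),
    I8 = c("constant", "patch"),
    I9 = c("patch", "patch"))
  lapply(combos, function(x) rd_structure(phi = x[1], lambda = x[2]))
}

#' Number of estimated parameters of a structure
#'
#' Factor contributions are 1 (constant), the number of landscapes
#' (landscape), or the number of patches (patch); each additive detection
#' block (p, and separately c) contributes
#' `1 + (n_patches - 1) + (n_sessions - 1)` parameters.
#'
#' @param structure An [rd_structure()].
#' @param n_patches Number of patches.
#' @param n_sessions Number of primary sessions.
#' @param n_landscapes Number of landscape classes (default 2).
#' @return Integer K.
#' @export
count_parameters <- function(structure, n_patches, n_sessions,
                             n_landscapes = 2L) {
  stopifnot(inherits(structure, "rd_structure"),
            n_patches >= 1, n_sessions >= 2)
  fac <- function(f) switch(f, constant = 1L,
                            landscape = as.integer(n_landscapes),
                            patch = as.integer(n_patches))
  det <- if (structure$detection == "patch_session")
    1L + (n_patches - 1L) + (n_sessions - 1L) else 1L
  as.integer(fac(structure$phi) + fac(structure$lambda) + 2L * det)
}

#' Session-level detection probability
#'
#' Probability of being caught at least once in a primary session given
#' per-occasion first-capture probabilities: `1 - prod(1 - p)`.
#'
#' @param p_occasions Vector of per-occasion capture probabilities in
#'   `[0, 1]`.
#' @return A probability.
#' @export
pstar <- function(p_occasions) {
  stopifnot(all(p_occasions >= 0), all(p_occasions <= 1))
  1 - prod(1 - p_occasions)
}

## sufficient statistics of one session's within-session histories:
## n caught, A = total occasions before first capture, R = recaptures,
## S = post-first-capture non-captures
session_stats <- function(histories) {
  histories <- matrix(histories, ncol = ncol(as.matrix(histories)))
  K <- ncol(histories)
  first <- apply(histories, 1, function(h) which(h == 1)[1])
  if (anyNA(first)) stop("every within-session history needs at least one 1")
  tot <- rowSums(histories)
  list(n = nrow(histories), K = K,
       A = sum(first - 1), R = sum(tot - 1),
       S = sum(K - first) - sum(tot - 1))
}

huggins_ll_stats <- function(st, p, c) {
  if (st$n == 0) return(0)
  ps <- 1 - (1 - p)^st$K
  st$A * log(1 - p) + st$n * log(p) +
    st$R * log(c) + st$S * log(1 - c) - st$n * log(ps)
}

#' Huggins conditional log-likelihood of one session
#'
#' Conditional likelihood of within-session capture histories given capture
#' at least once: an individual first caught at occasion j contributes
#' `(1-p)^(j-1) p * prod over later occasions of c^h (1-c)^(1-h)`, divided
#' by `p* = 1 - (1-p)^K`. Abundance is conditioned out of the likelihood
#' and recovered afterwards as M / p* ([huggins_abundance()]).
#'
#' @param histories Binary matrix, one row per captured individual, one
#'   column per secondary occasion; every row has at least one 1.
#' @param p First-capture probability per occasion, in (0, 1).
#' @param c Recapture probability per occasion, in (0, 1).
#' @return The conditional log-likelihood (0 for an empty session).
#' @export
huggins_session_loglik <- function(histories, p, c) {
  stopifnot(p > 0, p < 1, c > 0, c < 1)
  histories <- as.matrix(histories)
  if (nrow(histories) == 0) return(0)
  if (!all(histories %in% c(0, 1))) stop("histories must be binary")
  huggins_ll_stats(session_stats(histories), p, c)
}

#' Fit the Huggins closed-capture model to one session
#'
#' Two-parameter (p, c) maximum-likelihood fit of the conditional
#' within-session likelihood, with the derived abundance estimate.
#'
#' @param histories Binary matrix of within-session histories (rows =
#'   captured individuals).
#' @return List with p, c, pstar, loglik, vcov (logit scale) and the
#'   derived [huggins_abundance()] estimate.
#' @export
fit_huggins <- function(histories) {
  histories <- as.matrix(histories)
  st <- session_stats(histories)
  nll <- function(par)
    -huggins_ll_stats(st, stats::plogis(par[1]), stats::plogis(par[2]))
  opt <- stats::nlminb(c(0, 0), nll, lower = -12, upper = 12)
  H <- stats::optimHess(opt$par, nll)
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, 2, 2))
  p <- stats::plogis(opt$par[1]); c <- stats::plogis(opt$par[2])
  ps <- 1 - (1 - p)^st$K
  # delta method: d p* / d logit(p)
  dps <- st$K * (1 - p)^(st$K - 1) * p * (1 - p)
  var_ps <- dps^2 * V[1, 1]
  list(p = p, c = c, pstar = ps, loglik = -opt$objective,
       vcov = V, abundance = huggins_abundance(st$n, ps, var_ps))
}

#' Huggins abundance estimate from session detection
#'
#' `N_hat = M / p*` with a delta-method standard error combining binomial
#' sampling of M and the uncertainty of the detection parameters, and a
#' 95% confidence interval lognormal on `f0 = N_hat - M` so that the lower
#' bound never falls below the observed count M.
#'
#' @param M_t1 Number of distinct individuals caught in the session.
#' @param p_star Session-level detection probability in (0, 1].
#' @param var_pstar Variance of the estimated `p_star` (default 0).
#' @return A one-row data frame: M, pstar, N, se, lcl, ucl, unstable.
#' @export
huggins_abundance <- function(M_t1, p_star, var_pstar = 0) {
  stopifnot(M_t1 >= 0, p_star > 0, p_star <= 1)
  unstable <- p_star < 1e-6 && M_t1 > 0
  N <- M_t1 / p_star
  var_N <- M_t1 * (1 - p_star) / p_star^2 +
    M_t1^2 * var_pstar / p_star^4
  se <- sqrt(max(var_N, 0))
  f0 <- N - M_t1
  if (f0 > 1e-12 && se > 0) {
    C <- exp(1.96 * sqrt(log(1 + var_N / f0^2)))
    lcl <- M_t1 + f0 / C
    ucl <- M_t1 + f0 * C
  } else {
    lcl <- M_t1; ucl <- N + 1.96 * se
  }
  data.frame(M = M_t1, pstar = p_star, N = N, se = se,
             lcl = lcl, ucl = max(ucl, N), unstable = unstable)
}

#' Per-capita entry distribution implied by phi and lambda
#'
#' With expected relative population sizes `E_t = lambda^(t-1)`, expected
#' new entries are `B_1 = 1` and `B_t = E_t - phi * E_{t-1}`; the entry
#' distribution is `beta = B / sum(B)`. When lambda < phi the raw `B_t`
#' would be negative (growth slower than survival allows no recruitment);
#' they are floored at zero and the squared violation is returned as a
#' smooth penalty for the optimizer.
#'
#' @param phi Apparent survival per interval, in (0, 1].
#' @param lam Population rate of change per interval, > 0.
#' @param T_ Number of primary sessions.
#' @return List with `beta` (sums to 1), `penalty` (0 when lambda >= phi)
#'   and `floored` flag.
#' @export
entry_distribution <- function(phi, lam, T_) {
  stopifnot(phi > 0, phi <= 1, lam > 0, T_ >= 2)
  E <- lam^(seq_len(T_) - 1)
  B <- c(1, E[-1] - phi * E[-T_])
  viol <- pmax(-B, 0)
  B <- pmax(B, 0)
  list(beta = B / sum(B), penalty = sum(viol^2), floored = any(viol > 0))
}

## P(collapsed history h | entry/exit process) for one patch.
## patterns: U x T binary matrix of distinct observed session patterns.
open_pattern_probs <- function(patterns, phi, beta, ps) {
  T_ <- length(ps)
  apply(patterns, 1, function(h) {
    w <- which(h == 1)
    f <- w[1]; l <- w[length(w)]
    tot <- 0
    for (b in seq_len(f)) {
      for (d in l:T_) {
        surv <- phi^(d - b) * if (d < T_) (1 - phi) else 1
        seg <- b:d
        det <- prod(ifelse(h[seg] == 1, ps[seg], 1 - ps[seg]))
        tot <- tot + beta[b] * surv * det
      }
    }
    tot
  })
}

open_prob_never <- function(phi, beta, ps) {
  T_ <- length(ps)
  tot <- 0
  for (b in seq_len(T_)) {
    for (d in b:T_) {
      surv <- phi^(d - b) * if (d < T_) (1 - phi) else 1
      tot <- tot + beta[b] * surv * prod(1 - ps[b:d])
    }
  }
  tot
}

#' Open-process conditional log-likelihood of collapsed histories
#'
#' Likelihood of session-level detection histories under entry (governed by
#' the [entry_distribution()] of phi and lambda), survival phi per
#' interval, and session detection probabilities `p*_t`, conditioned on
#' being detected at least once. Summing the conditional probabilities of
#' all 2^T - 1 observable histories gives exactly 1.
#'
#' @param detected Binary matrix, one row per individual, one column per
#'   primary session; every row has at least one 1.
#' @param phi Apparent survival per interval, in (0, 1].
#' @param lam Population rate of change, > 0.
#' @param pstar_by_session Vector of session detection probabilities in
#'   (0, 1).
#' @return The conditional log-likelihood (0 for no individuals).
#' @export
open_history_loglik <- function(detected, phi, lam, pstar_by_session) {
  detected <- as.matrix(detected)
  if (nrow(detected) == 0) return(0)
  stopifnot(ncol(detected) == length(pstar_by_session),
            all(detected %in% c(0, 1)), all(rowSums(detected) >= 1),
            all(pstar_by_session > 0), all(pstar_by_session < 1))
  ed <- entry_distribution(phi, lam, ncol(detected))
  pr <- open_pattern_probs(detected, phi, ed$beta, pstar_by_session)
  denom <- 1 - open_prob_never(phi, ed$beta, pstar_by_session)
  sum(log(pr)) - nrow(detected) * log(denom)
}

## ---- joint fit ----------------------------------------------------------

## precomputed indicator representation of the open-process sums: one row
## per (pattern, entry b, exit d) triple so that a likelihood evaluation is
## a matrix product with the log detection probabilities
open_precompute <- function(patterns, T_) {
  n_pat <- nrow(patterns)
  pat_idx <- integer(0); bvec <- integer(0); dvec <- integer(0)
  pos <- list(); neg <- list()
  for (u in seq_len(n_pat)) {
    h <- patterns[u, ]
    w <- which(h == 1)
    f <- w[1]; l <- w[length(w)]
    for (b in seq_len(f)) {
      for (d in l:T_) {
        pat_idx <- c(pat_idx, u); bvec <- c(bvec, b); dvec <- c(dvec, d)
        seg <- rep(0L, T_); seg[b:d] <- 1L
        pos[[length(pos) + 1L]] <- seg * h
        neg[[length(neg) + 1L]] <- seg * (1L - h)
      }
    }
  }
  # never-detected pairs (for the conditioning denominator)
  b0 <- integer(0); d0 <- integer(0); neg0 <- list()
  for (b in seq_len(T_)) {
    for (d in b:T_) {
      b0 <- c(b0, b); d0 <- c(d0, d)
      seg <- rep(0L, T_); seg[b:d] <- 1L
      neg0[[length(neg0) + 1L]] <- seg
    }
  }
  list(n_pat = n_pat, pat_idx = pat_idx, bvec = bvec, dvec = dvec,
       last = dvec == T_,
       Ipos = do.call(rbind, pos), Ineg = do.call(rbind, neg),
       b0 = b0, d0 = d0, last0 = d0 == T_, Ineg0 = do.call(rbind, neg0))
}

## conditional open-process loglik from a precomputed pattern structure
open_loglik_pre <- function(pre, counts, phi, beta, ps) {
  if (pre$n_pat == 0) return(list(ll = 0))
  lp <- log(ps); lq <- log1p(-ps)
  det <- exp(drop(pre$Ipos %*% lp + pre$Ineg %*% lq))
  coef <- beta[pre$bvec] * phi^(pre$dvec - pre$bvec)
  coef[!pre$last] <- coef[!pre$last] * (1 - phi)
  pr <- drop(rowsum(coef * det, pre$pat_idx))
  coef0 <- beta[pre$b0] * phi^(pre$d0 - pre$b0)
  coef0[!pre$last0] <- coef0[!pre$last0] * (1 - phi)
  p0 <- sum(coef0 * exp(drop(pre$Ineg0 %*% lq)))
  list(ll = sum(counts * log(pr)) - sum(counts) * log1p(-p0))
}

## per-patch sufficient statistics for the joint likelihood, with the
## open-process (pattern, entry, exit) triples of all patches stacked into
## global indicator matrices so one evaluation is a pair of matrix products
rd_stats <- function(data) {
  des <- data$design
  T_ <- des$n_primary; K <- des$n_secondary
  G <- nrow(des$patches)
  Amat <- nmat <- Rmat <- Smat <- matrix(0, G, T_)
  patterns <- vector("list", G)
  pat_counts <- vector("list", G)
  M <- mt1_per_session(data)
  gv <- bv <- dv <- pidx <- integer(0)
  g0 <- b0 <- d0 <- integer(0)
  pos_rows <- list(); neg_rows <- list(); neg0_rows <- list()
  counts_all <- integer(0)
  n_open <- integer(0)
  pat_offset <- 0L
  for (g in seq_len(G)) {
    pid <- des$patches$patch_id[g]
    inds <- Filter(function(x) x$patch_id == pid, data$individuals)
    for (t in seq_len(T_)) {
      rows <- lapply(inds, function(x) x$enc[t, ])
      rows <- rows[vapply(rows, sum, numeric(1)) > 0]
      if (length(rows)) {
        s <- session_stats(do.call(rbind, rows))
        Amat[g, t] <- s$A; nmat[g, t] <- s$n
        Rmat[g, t] <- s$R; Smat[g, t] <- s$S
      }
    }
    if (length(inds)) {
      det <- t(vapply(inds, function(x) as.integer(rowSums(x$enc) > 0),
                      integer(T_)))
      key <- apply(det, 1, paste, collapse = "")
      tab <- table(key)
      patterns[[g]] <- do.call(rbind, lapply(names(tab), function(k)
        as.integer(strsplit(k, "")[[1]])))
      pat_counts[[g]] <- as.integer(tab)
    } else {
      patterns[[g]] <- matrix(integer(0), 0, T_)
      pat_counts[[g]] <- integer(0)
      next
    }
    pre <- open_precompute(patterns[[g]], T_)
    embed <- function(m) {
      out <- matrix(0L, nrow(m), G * T_)
      out[, (g - 1L) * T_ + seq_len(T_)] <- m
      out
    }
    pos_rows[[length(pos_rows) + 1L]] <- embed(pre$Ipos)
    neg_rows[[length(neg_rows) + 1L]] <- embed(pre$Ineg)
    neg0_rows[[length(neg0_rows) + 1L]] <- embed(pre$Ineg0)
    gv <- c(gv, rep(g, length(pre$bvec)))
    bv <- c(bv, pre$bvec); dv <- c(dv, pre$dvec)
    pidx <- c(pidx, pre$pat_idx + pat_offset)
    pat_offset <- pat_offset + pre$n_pat
    g0 <- c(g0, rep(g, length(pre$b0)))
    b0 <- c(b0, pre$b0); d0 <- c(d0, pre$d0)
    counts_all <- c(counts_all, pat_counts[[g]])
    n_open <- c(n_open, sum(pat_counts[[g]]))
  }
  bind0 <- function(lst) if (length(lst)) do.call(rbind, lst)
                         else matrix(0L, 0, G * T_)
  list(design = des, G = G, T_ = T_, K = K, M = M,
       A = Amat, n = nmat, R = Rmat, S = Smat,
       patterns = patterns, pat_counts = pat_counts,
       Gpos = bind0(pos_rows), Gneg = bind0(neg_rows),
       Gneg0 = bind0(neg0_rows),
       gv = gv, bv = bv, dv = dv, lastv = dv == T_, pidx = pidx,
       g0 = g0, b0 = b0, d0 = d0, last0 = d0 == T_,
       counts_all = counts_all, n_open = n_open,
       n_ind = length(data$individuals))
}

## parameter-vector layout for a structure
rd_param_map <- function(structure, design) {
  G <- nrow(design$patches)
  T_ <- design$n_primary
  ls_idx <- patch_landscape_index(design)
  nL <- length(unique(ls_idx))
  fac_n <- function(f) switch(f, constant = 1L, landscape = nL, patch = G)
  fac_map <- function(f) switch(f, constant = rep(1L, G),
                                landscape = ls_idx, patch = seq_len(G))
  n_phi <- fac_n(structure$phi); n_lam <- fac_n(structure$lambda)
  n_det <- if (structure$detection == "patch_session")
    1L + (G - 1L) + (T_ - 1L) else 1L
  list(G = G, T_ = T_, n_phi = n_phi, n_lam = n_lam, n_det = n_det,
       phi_map = fac_map(structure$phi), lam_map = fac_map(structure$lambda),
       npar = n_phi + n_lam + 2L * n_det)
}

## decode parameter vector -> real-scale phi/lam per patch, p/c matrices GxT
rd_decode <- function(par, map, structure) {
  i <- 0L
  phi_eta <- par[i + seq_len(map$n_phi)]; i <- i + map$n_phi
  lam_eta <- par[i + seq_len(map$n_lam)]; i <- i + map$n_lam
  p_eta <- par[i + seq_len(map$n_det)]; i <- i + map$n_det
  c_eta <- par[i + seq_len(map$n_det)]
  det_mat <- function(eta) {
    if (structure$detection == "patch_session") {
      a <- c(0, eta[1L + seq_len(map$G - 1L)])
      b <- c(0, eta[1L + (map$G - 1L) + seq_len(map$T_ - 1L)])
      stats::plogis(eta[1L] + outer(a, b, `+`))
    } else {
      matrix(stats::plogis(eta[1L]), map$G, map$T_)
    }
  }
  list(phi = stats::plogis(phi_eta)[map$phi_map],
       lam = exp(lam_eta)[map$lam_map],
       p = det_mat(p_eta), c = det_mat(c_eta))
}

rd_negloglik <- function(par, st, map, structure, penalty_weight = 100) {
  th <- rd_decode(par, map, structure)
  # Huggins part, all patches and sessions at once
  psess <- 1 - (1 - th$p)^st$K
  ll <- sum(st$A * log1p(-th$p) + st$n * log(th$p) +
            st$R * log(th$c) + st$S * log1p(-th$c) -
            st$n * log(psess))
  pen <- 0
  if (length(st$gv)) {
    T_ <- st$T_
    phiv <- th$phi; lamv <- th$lam
    # entry distributions of all patches at once (floored, with penalty)
    Emat <- outer(lamv, 0:(T_ - 1), `^`)
    Bmat <- cbind(1, Emat[, -1, drop = FALSE] -
                    phiv * Emat[, -T_, drop = FALSE])
    pen <- sum(pmax(-Bmat, 0)^2)
    Bmat[Bmat < 0] <- 0
    betaM <- Bmat / rowSums(Bmat)
    lpv <- as.vector(t(log(psess)))
    lqv <- as.vector(t(log1p(-psess)))
    det <- exp(drop(st$Gpos %*% lpv + st$Gneg %*% lqv))
    coef <- betaM[cbind(st$gv, st$bv)] * phiv[st$gv]^(st$dv - st$bv)
    nl <- !st$lastv
    coef[nl] <- coef[nl] * (1 - phiv[st$gv[nl]])
    pr <- drop(rowsum(coef * det, st$pidx))
    det0 <- exp(drop(st$Gneg0 %*% lqv))
    coef0 <- betaM[cbind(st$g0, st$b0)] * phiv[st$g0]^(st$d0 - st$b0)
    nl0 <- !st$last0
    coef0[nl0] <- coef0[nl0] * (1 - phiv[st$g0[nl0]])
    p0 <- drop(rowsum(coef0 * det0, st$g0))
    ll <- ll + sum(st$counts_all * log(pr)) -
      sum(st$n_open * log1p(-p0))
  }
  if (!is.finite(ll)) return(1e10)
  -ll + penalty_weight * pen
}

#' Fit a robust-design model
#'
#' Joint maximum-likelihood fit of a parameter structure: Huggins
#' conditional likelihoods within every patch x primary session plus the
#' open-process likelihood on collapsed histories per patch, with
#' session-level detection `p*_t` computed from the same capture rates.
#' Optimization runs from a null start and `n_random_starts` seeded random
#' starts, keeping the best optimum; the variance matrix is the inverse of
#' the observed information.
#'
#' @param data An [rd_data()] object with at least 2 primary sessions.
#' @param structure An [rd_structure()].
#' @param n_random_starts Number of extra random starts (default 5).
#' @param seed Seed for the random starts.
#' @param ess AICc effective sample size; default is the total number of
#'   captured individuals.
#' @param start Optional starting vector on the link scale (prepended to
#'   the null and random starts).
#' @return An object of class `rd_fit`: parameter estimates and vcov on
#'   the link scale, loglik, K, AICc, real-scale per-patch phi and lambda
#'   with delta-method SEs and 95% CIs, and per patch x session abundance
#'   estimates ([huggins_abundance()]).
#' @export
fit_robust_design <- function(data, structure, n_random_starts = 5,
                              seed = NULL, ess = NULL, start = NULL) {
  stopifnot(inherits(data, "rd_data"), inherits(structure, "rd_structure"))
  st <- rd_stats(data)
  map <- rd_param_map(structure, data$design)
  nll <- function(par) rd_negloglik(par, st, map, structure)
  if (!is.null(seed)) set.seed(seed)
  starts <- list(rep(0, map$npar))
  if (!is.null(start)) {
    stopifnot(length(start) == map$npar)
    starts <- c(list(start), starts)
  }
  for (r in seq_len(n_random_starts))
    starts[[length(starts) + 1L]] <- stats::runif(map$npar, -1.5, 1.5)
  best <- NULL
  for (s in starts) {
    opt <- stats::nlminb(s, nll, lower = -12, upper = 12,
                         control = list(iter.max = 1000, eval.max = 2000,
                                        rel.tol = 1e-9))
    if (is.null(best) || opt$objective < best$objective) best <- opt
    # a warm start that already converged makes further starts redundant
    if (!is.null(start) && n_random_starts == 0) break
  }
  converged <- best$convergence == 0 && best$objective < 1e9
  V <- matrix(NA_real_, map$npar, map$npar)
  if (converged) {
    H <- tryCatch(stats::optimHess(best$par, nll), error = function(e) NULL)
    if (!is.null(H))
      V <- tryCatch(solve(H), error = function(e) V)
    if (!anyNA(V) && any(diag(V) < 0)) V[] <- NA_real_
  }
  K <- count_parameters(structure, map$G, st$T_,
                        length(unique(data$design$patches$landscape)))
  stopifnot(K == map$npar)
  if (is.null(ess)) ess <- st$n_ind
  loglik <- -best$objective
  th <- rd_decode(best$par, map, structure)
  fit <- list(structure = structure, design = data$design, par = best$par,
              vcov = V, map = map, loglik = loglik, K = K, ess = ess,
              AICc = if (ess > K + 1) aicc(loglik, K, ess) else NA_real_,
              deviance = -2 * loglik, converged = converged,
              theta = th, stats = st)
  class(fit) <- "rd_fit"
  fit$real <- rd_real_estimates(fit)
  fit$abundance <- rd_abundance(fit)
  fit
}

#' @export
print.rd_fit <- function(x, ...) {
  cat("Robust-design fit:", structure_label(x$structure),
      sprintf("\n  K = %d, logLik = %.3f, AICc = %.3f, converged = %s\n",
              x$K, x$loglik, x$AICc, x$converged))
  invisible(x)
}

## real-scale phi / lambda per patch with delta-method SE and 95% CI
rd_real_estimates <- function(fit) {
  map <- fit$map; des <- fit$design
  se_eta <- function(idx) {
    if (anyNA(fit$vcov)) rep(NA_real_, length(idx))
    else sqrt(diag(fit$vcov)[idx])
  }
  phi_idx <- seq_len(map$n_phi)[map$phi_map]
  lam_idx <- (map$n_phi + seq_len(map$n_lam))[map$lam_map]
  phi_eta <- fit$par[phi_idx]; phi_se_eta <- se_eta(phi_idx)
  lam_eta <- fit$par[lam_idx]; lam_se_eta <- se_eta(lam_idx)
  phi <- stats::plogis(phi_eta)
  lam <- exp(lam_eta)
  data.frame(
    patch_id = des$patches$patch_id, landscape = des$patches$landscape,
    phi = phi, phi_se = phi * (1 - phi) * phi_se_eta,
    phi_lcl = stats::plogis(phi_eta - 1.96 * phi_se_eta),
    phi_ucl = stats::plogis(phi_eta + 1.96 * phi_se_eta),
    lambda = lam, lambda_se = lam * lam_se_eta,
    lambda_lcl = exp(lam_eta - 1.96 * lam_se_eta),
    lambda_ucl = exp(lam_eta + 1.96 * lam_se_eta),
    stringsAsFactors = FALSE)
}

## per patch x session Huggins abundance under the fitted detection model
rd_abundance <- function(fit) {
  st <- fit$stats; map <- fit$map
  th <- fit$theta
  out <- list()
  for (g in seq_len(st$G)) {
    for (t in seq_len(st$T_)) {
      ps <- 1 - (1 - th$p[g, t])^st$K
      var_ps <- rd_pstar_var(fit, g, t)
      ab <- huggins_abundance(st$M[g, t], ps, var_ps)
      ab$patch_id <- fit$design$patches$patch_id[g]
      ab$session <- t
      out[[length(out) + 1L]] <- ab
    }
  }
  out <- do.call(rbind, out)
  out[c("patch_id", "session", "M", "pstar", "N", "se", "lcl", "ucl",
        "unstable")]
}

## delta-method variance of p*_{g,t} via numeric gradient in the p block
rd_pstar_var <- function(fit, g, t) {
  if (anyNA(fit$vcov)) return(0)
  map <- fit$map
  idx <- map$n_phi + map$n_lam + seq_len(map$n_det)
  f <- function(par) {
    th <- rd_decode(par, map, fit$structure)
    1 - (1 - th$p[g, t])^fit$stats$K
  }
  gr <- numeric(length(fit$par))
  h <- 1e-5
  for (j in idx) {
    up <- fit$par; up[j] <- up[j] + h
    dn <- fit$par; dn[j] <- dn[j] - h
    gr[j] <- (f(up) - f(dn)) / (2 * h)
  }
  max(drop(t(gr) %*% fit$vcov %*% gr), 0)
}

## link-scale start vector for `structure` assembled from a reference fit
## on the same data (level starts = mean of the reference's per-patch
## link-scale estimates; detection blocks copied verbatim)
warm_start_from <- function(ref, structure, design) {
  map_new <- rd_param_map(structure, design)
  clamp <- function(x) pmin(pmax(x, -11), 11)
  phi_eta <- clamp(stats::qlogis(ref$theta$phi))
  lam_eta <- clamp(log(ref$theta$lam))
  lvl <- function(eta, fmap, n)
    vapply(seq_len(n), function(l) mean(eta[fmap == l]), numeric(1))
  old <- ref$map
  det_idx <- old$n_phi + old$n_lam + seq_len(2L * old$n_det)
  if (map_new$n_det != old$n_det) return(NULL)
  c(lvl(phi_eta, map_new$phi_map, map_new$n_phi),
    lvl(lam_eta, map_new$lam_map, map_new$n_lam),
    ref$par[det_idx])
}

#' Fit a set of candidate structures and rank by AICc
#'
#' Fits each structure, drops non-converged fits with a warning, and ranks
#' the rest by AICc with Delta and Akaike weights. The effective sample
#' size is the total number of captured individuals and is shared by all
#' models.
#'
#' @param data An [rd_data()] object.
#' @param structures Named list of [rd_structure()]s, default
#'   [rd_structures()].
#' @inheritParams fit_robust_design
#' @return A list of class `rd_fit_set` with `table` (model, K, loglik,
#'   AICc, delta, weight, deviance) and `fits`.
#' @export
fit_rd_set <- function(data, structures = rd_structures(),
                       n_random_starts = 5, seed = NULL) {
  fits <- list()
  ref <- NULL
  for (nm in names(structures)) {
    start <- if (!is.null(ref))
      warm_start_from(ref, structures[[nm]], data$design) else NULL
    f <- fit_robust_design(data, structures[[nm]],
                           n_random_starts = n_random_starts, seed = seed,
                           start = start)
    if (!f$converged) {
      warning("structure ", nm, " did not converge; dropped")
      next
    }
    if (is.null(ref)) ref <- f
    fits[[nm]] <- f
  }
  if (!length(fits)) stop("no structure converged")
  tab <- akaike_weights(vapply(fits, `[[`, numeric(1), "AICc"),
                        model = names(fits))
  tab$K <- vapply(fits, `[[`, integer(1), "K")[tab$model]
  tab$loglik <- vapply(fits, `[[`, numeric(1), "loglik")[tab$model]
  tab$deviance <- -2 * tab$loglik
  tab <- tab[c("model", "K", "loglik", "AICc", "delta", "weight",
               "deviance")]
  rownames(tab) <- NULL
  out <- list(table = tab, fits = fits)
  class(out) <- "rd_fit_set"
  out
}

#' Model-averaged demographic estimates
#'
#' Averages per-patch phi and lambda and per patch x session abundance
#' across the fitted structures with Akaike weights, reporting
#' unconditional standard errors ([model_average()]). Abundance confidence
#' intervals are lognormal on `f0 = N - M`; phi and lambda intervals are
#' normal on the real scale, clipped to their admissible ranges.
#'
#' @param fitset An `rd_fit_set` from [fit_rd_set()].
#' @return A list with data frames `phi_lambda` (per patch) and
#'   `abundance` (per patch x session).
#' @export
rd_model_average <- function(fitset) {
  stopifnot(inherits(fitset, "rd_fit_set"))
  tab <- fitset$table
  w <- tab$weight; names(w) <- tab$model
  fits <- fitset$fits[tab$model]
  des <- fits[[1]]$design
  G <- nrow(des$patches)
  avg_par <- function(getter, se_getter) {
    est <- matrix(unlist(lapply(fits, getter)), nrow = G)
    se <- matrix(unlist(lapply(fits, se_getter)), nrow = G)
    se[is.na(se)] <- 0
    t(sapply(seq_len(G), function(i)
      unlist(model_average(est[i, ], se[i, ]^2, w))))
  }
  pl <- avg_par(function(f) f$real$phi, function(f) f$real$phi_se)
  lm_ <- avg_par(function(f) f$real$lambda, function(f) f$real$lambda_se)
  phi_lambda <- data.frame(
    patch_id = des$patches$patch_id, landscape = des$patches$landscape,
    phi = pl[, 1], phi_se = pl[, 2],
    phi_lcl = pmax(pl[, 1] - 1.96 * pl[, 2], 0),
    phi_ucl = pmin(pl[, 1] + 1.96 * pl[, 2], 1),
    lambda = lm_[, 1], lambda_se = lm_[, 2],
    lambda_lcl = pmax(lm_[, 1] - 1.96 * lm_[, 2], 0),
    lambda_ucl = lm_[, 1] + 1.96 * lm_[, 2],
    stringsAsFactors = FALSE)
  ab0 <- fits[[1]]$abundance
  rows <- lapply(seq_len(nrow(ab0)), function(i) {
    est <- vapply(fits, function(f) f$abundance$N[i], numeric(1))
    se <- vapply(fits, function(f) f$abundance$se[i], numeric(1))
    av <- model_average(est, se^2, w)
    M <- ab0$M[i]
    f0 <- av$estimate - M
    if (f0 > 1e-12 && av$se > 0) {
      C <- exp(1.96 * sqrt(log(1 + av$se^2 / f0^2)))
      lcl <- M + f0 / C; ucl <- M + f0 * C
    } else {
      lcl <- M; ucl <- av$estimate + 1.96 * av$se
    }
    data.frame(patch_id = ab0$patch_id[i], session = ab0$session[i],
               M = M, N = av$estimate, se = av$se,
               lcl = lcl, ucl = max(ucl, av$estimate),
               stringsAsFactors = FALSE)
  })
  list(phi_lambda = phi_lambda,
       abundance = do.call(rbind, c(rows, make.row.names = FALSE)))
}
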