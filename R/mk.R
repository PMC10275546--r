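# Build a rate matrix from a structure label and free-rate vector.
# Off-diagonal fill order: ER one shared rate; SYM upper triangle by rows
# (i<j), mirrored; ARD all off-diagonals by rows.
build_Q <- function(states, structure, rates) {
  k <- length(states)
  Q <- matrix(0, k, k, dimnames = list(states, states))
  idx <- which(row(Q) != col(Q))
  if (structure == "ER") {
    stopifnot(length(rates) == 1L)
    Q[idx] <- rates
  } else if (structure == "SYM") {
    stopifnot(length(rates) == k * (k - 1) / 2)
    r <- 1L
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      Q[i, j] <- Q[j, i] <- rates[r]; r <- r + 1L
    }
  } else if (structure == "ARD") {
    stopifnot(length(rates) == k * (k - 1))
    r <- 1L
    for (i in seq_len(k)) for (j in seq_len(k)) if (i != j) {
      Q[i, j] <- rates[r]; r <- r + 1L
    }
  } else stop("unknown rate structure: ", structure)
  diag(Q) <- -rowSums(Q)
  Q
}

n_free_rates <- function(structure, k) {
  as.integer(switch(structure, ER = 1L, SYM = k * (k - 1L) / 2L,
                    ARD = k * (k - 1L),
                    stop("unknown rate structure: ", structure)))
}

# Stationary distribution of a CTMC generator (left null vector, sums to 1).
stationary_dist <- function(Q) {
  k <- nrow(Q)
  A <- rbind(t(Q), rep(1, k))
  b <- c(rep(0, k), 1)
  pi <- qr.solve(A, b)
  pi <- pmax(pi, 0)
  pi / sum(pi)
}

resolve_root_prior <- function(root_prior, Q, states) {
  if (is.numeric(root_prior)) {
    stopifnot(length(root_prior) == length(states))
    p <- root_prior / sum(root_prior)
  } else if (identical(root_prior, "flat")) {
    p <- rep(1 / length(states), length(states))
  } else if (identical(root_prior, "stationary")) {
    p <- stationary_dist(Q)
  } else stop("root_prior must be 'stationary', 'flat', or a numeric vector")
  names(p) <- states
  p
}

# Transition probability matrices for all edges, as a k x k x E array.
edge_pmats <- function(Q, edge_lengths) {
  k <- nrow(Q)
  P <- array(0, dim = c(k, k, length(edge_lengths)))
  for (e in seq_along(edge_lengths)) P[, , e] <- ape::matexpo(Q * edge_lengths[e])
  # guard tiny negative entries from the expm series
  P[P < 0] <- 0
  P
}

tip_state_matrix <- function(tr, tip_states, states) {
  ntip <- ape::Ntip(tr)
  st <- tip_states[tr$tip.label]
  if (anyNA(st)) stop("every tip needs a state; missing for: ",
                      paste(tr$tip.label[is.na(st)], collapse = ", "))
  if (!all(st %in% states)) stop("unknown state label: ",
                                 paste(setdiff(unique(st), states), collapse = ", "))
  L <- matrix(0, ntip, length(states), dimnames = list(tr$tip.label, states))
  L[cbind(seq_len(ntip), match(st, states))] <- 1
  L
}

# Felsenstein pruning: per-node conditional likelihoods with log-scaling.
# Returns list(partials = (Ntip+Nnode) x k matrix, logscale = per-node log
# scaling, P = edge pmats, order = postorder edge indices).
mk_partials <- function(tr, tip_states, Q, states) {
  ntip <- ape::Ntip(tr); nn <- ntip + tr$Nnode
  k <- length(states)
  P <- edge_pmats(Q, tr$edge.length)
  D <- matrix(1, nn, k)
  D[seq_len(ntip), ] <- tip_state_matrix(tr, tip_states, states)
  lsc <- numeric(nn)
  ord <- ape::reorder.phylo(tr, "postorder", index.only = TRUE)
  for (e in ord) {
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    msg <- as.vector(P[, , e] %*% D[ch, ])
    D[par, ] <- D[par, ] * msg
    lsc[par] <- lsc[par] + lsc[ch]
    mx <- max(D[par, ])
    if (mx > 0 && (mx < 1e-100 || mx > 1e100)) {
      D[par, ] <- D[par, ] / mx
      lsc[par] <- lsc[par] + log(mx)
    }
  }
  list(partials = D, logscale = lsc, P = P, postorder = ord)
}

#' Mk log-likelihood by Felsenstein pruning
#'
#' @param tr A tree with branch lengths.
#' @param tip_states Named character vector of states, one per tip.
#' @param structure \code{"ER"}, \code{"SYM"}, or \code{"ARD"}.
#' @param rates Free rate vector for the structure (per unit tree height).
#' @param root_prior \code{"stationary"} (default), \code{"flat"}, or a
#'   probability vector over states.
#' @param states Optional state set; defaults to sorted observed states.
#' @return Log-likelihood (scalar).
#' @export
mk_loglik <- function(tr, tip_states, structure = "ER", rates,
                      root_prior = "stationary", states = NULL) {
  if (is.null(states)) states <- sort(unique(as.character(tip_states)))
  if (any(rates < 0)) stop("rates must be >= 0")
  Q <- build_Q(states, structure, rates)
  pr <- resolve_root_prior(root_prior, Q, states)
  pp <- mk_partials(tr, tip_states, Q, states)
  root <- ape::Ntip(tr) + 1L
  lik <- sum(pr * pp$partials[root, ])
  log(lik) + pp$logscale[root]
}

#' Fit an Mk model by maximum likelihood
#'
#' Rates are optimized on the log scale (bounds \code{[1e-8, 1e3]} per unit
#' tree height) with three starting points. With \code{structure = "auto"}
#' all three rate structures are fitted and the lowest-AICc fit is returned;
#' AICc uses \code{k} = number of free rates and \code{n} = number of tips.
#'
#' @inheritParams mk_loglik
#' @param structure \code{"auto"}, \code{"ER"}, \code{"SYM"}, or
#'   \code{"ARD"}.
#' @return An \code{mk_fit}: states, structure, rates, \code{Q},
#'   \code{logLik}, \code{AICc}, root prior used, and (for
#'   \code{"auto"}) the per-structure AICc table in \code{$candidates}.
#' @export
fit_mk <- function(tr, tip_states, structure = "auto",
                   root_prior = "stationary", states = NULL) {
  if (is.null(states)) states <- sort(unique(as.character(tip_states)))
  if (length(states) < 2L)
    stop("degenerate character: fewer than 2 observed states")
  if (structure == "auto") {
    fits <- lapply(c("ER", "SYM", "ARD"), function(s)
      fit_mk(tr, tip_states, s, root_prior, states))
    aiccs <- vapply(fits, function(f) f$AICc, 0)
    best <- fits[[which.min(aiccs)]]
    best$candidates <- data.frame(structure = c("ER", "SYM", "ARD"),
                                  logLik = vapply(fits, function(f) f$logLik, 0),
                                  k = vapply(fits, function(f) f$k_free, 0L),
                                  AICc = aiccs)
    return(best)
  }
  np <- n_free_rates(structure, length(states))
  nll <- function(lr) {
    ll <- tryCatch(mk_loglik(tr, tip_states, structure, exp(lr), root_prior, states),
                   error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  starts <- lapply(c(0.1, 1, 5), function(r0) rep(log(r0), np))
  best <- NULL
  for (st in starts) {
    o <- tryCatch(
      stats::optim(st, nll, method = "L-BFGS-B",
                   lower = rep(log(1e-8), np), upper = rep(log(1e3), np)),
      error = function(e) NULL)
    if (is.null(o)) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best))
    stop("rate optimization failed for structure ", structure)
  rates <- exp(best$par)
  ll <- -best$value
  n <- ape::Ntip(tr)
  aicc <- -2 * ll + 2 * np + 2 * np * (np + 1) / (n - np - 1)
  Q <- build_Q(states, structure, rates)
  out <- list(states = states, structure = structure, rates = rates, Q = Q,
              logLik = ll, AICc = aicc, k_free = np, n_tips = n,
              root_prior = resolve_root_prior(root_prior, Q, states),
              root_prior_kind = if (is.character(root_prior)) root_prior else "fixed")
  class(out) <- "mk_fit"
  out
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("Mk fit:", x$structure, "on", length(x$states), "states;",
      "lnL =", format(x$logLik, digits = 6), " AICc =", format(x$AICc, digits = 6), "\n")
  cat("rates:", format(x$rates, digits = 4), "\n")
  invisible(x)
}

#' Marginal ancestral states and MAP labels
#'
#' Computes exact marginal posterior state distributions for every node by a
#' down-pass (pruning) and up-pass message schedule, then the maximum a
#' posteriori label per node with lexicographic tie-breaking.
#'
#' @param fit An \code{mk_fit}.
#' @param tr The tree.
#' @param tip_states Named tip-state vector.
#' @return List with \code{marginal} ((Ntip+Nnode) x k matrix, rows sum to
#'   1) and \code{map} (character vector of MAP labels per node).
#' @export
ancestral_states <- function(fit, tr, tip_states) {
  states <- fit$states
  ntip <- ape::Ntip(tr); nn <- ntip + tr$Nnode
  pp <- mk_partials(tr, tip_states, fit$Q, states)
  D <- pp$partials; P <- pp$P
  root <- ntip + 1L
  # up-pass messages F[v]: prior at the root, then propagated tipward
  Fm <- matrix(0, nn, length(states))
  Fm[root, ] <- fit$root_prior
  kids <- split(seq_len(nrow(tr$edge)), tr$edge[, 1])
  # preorder over edges: parents before children
  pre <- rev(pp$postorder)
  for (e in pre) {
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    sibs <- setdiff(kids[[as.character(par)]], e)
    above <- Fm[par, ]
    for (se in sibs) above <- above * as.vector(P[, , se] %*% D[tr$edge[se, 2], ])
    Fm[ch, ] <- as.vector(crossprod(P[, , e], above))
    mx <- max(Fm[ch, ])
    if (mx > 0) Fm[ch, ] <- Fm[ch, ] / mx
  }
  marg <- Fm * D
  marg <- marg / rowSums(marg)
  colnames(marg) <- states
  map <- states[apply(marg, 1, which.max)]  # states sorted => lexicographic ties
  list(marginal = marg, map = map)
}

# Sample a CTMC path on one branch conditioned on endpoints, by
# uniformization. Returns named numeric vector of segment lengths
# (parent-to-child order).
sample_branch_path <- function(Q, states, a, b, len, Pab) {
  k <- nrow(Q)
  mu <- max(-diag(Q))
  ia <- match(a, states); ib <- match(b, states)
  if (mu * len < 1e-12) {
    seg <- len; names(seg) <- b
    return(seg)
  }
  R <- diag(k) + Q / mu
  # sample number of uniformized jumps N | endpoints
  u <- stats::runif(1) * Pab
  Rn <- diag(k)          # R^0
  pows <- list(Rn)
  n <- 0L
  acc <- stats::dpois(0, mu * len) * (ia == ib)
  while (acc < u && n < 1000L) {
    n <- n + 1L
    Rn <- Rn %*% R
    pows[[n + 1L]] <- Rn
    acc <- acc + stats::dpois(n, mu * len) * Rn[ia, ib]
  }
  if (n == 0L) { seg <- len; names(seg) <- b; return(seg) }
  # state sequence at the n jump epochs
  seq_states <- integer(n + 1L); seq_states[1] <- ia; seq_states[n + 1L] <- ib
  if (n > 1L) for (m in seq_len(n - 1L)) {
    cur <- seq_states[m]
    w <- R[cur, ] * pows[[n - m + 1L]][, ib]   # R^(n-m) remaining
    seq_states[m + 1L] <- sample.int(k, 1L, prob = w)
  }
  times <- sort(stats::runif(n)) * len
  bounds <- c(0, times, len)
  segs <- diff(bounds)
  labs <- states[seq_states]
  keep <- c(TRUE, labs[-1] != labs[-length(labs)])
  g <- cumsum(keep)
  out <- as.numeric(tapply(segs, g, sum))
  names(out) <- labs[keep]
  out
}

#' Stochastic character maps
#'
#' Samples complete regime histories conditioned on the tip data under a
#' fitted Mk model: joint node states by backward sampling from the pruning
#' partials, then within-branch histories by uniformization conditioned on
#' the endpoints. Reproducible under \code{seed}.
#'
#' @param fit An \code{mk_fit}.
#' @param tr The tree.
#' @param tip_states Named tip-state vector.
#' @param n_maps Number of maps (>= 1).
#' @param seed Optional integer seed.
#' @return List of \code{regime_painting} objects; each carries the sampled
#'   \code{node_states}.
#' @export
stochastic_maps <- function(fit, tr, tip_states, n_maps = 1L, seed = NULL) {
  stopifnot(n_maps >= 1L)
  if (!is.null(seed)) set.seed(seed)
  states <- fit$states
  ntip <- ape::Ntip(tr); nn <- ntip + tr$Nnode
  pp <- mk_partials(tr, tip_states, fit$Q, states)
  D <- pp$partials; P <- pp$P
  root <- ntip + 1L
  pre <- rev(pp$postorder)
  lapply(seq_len(n_maps), function(i) {
    ns <- integer(nn)
    w <- fit$root_prior * D[root, ]
    ns[root] <- sample.int(length(states), 1L, prob = w)
    for (e in pre) {
      par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      w <- P[ns[par], , e] * D[ch, ]
      ns[ch] <- sample.int(length(states), 1L, prob = w)
    }
    maps <- lapply(seq_len(nrow(tr$edge)), function(e) {
      a <- states[ns[tr$edge[e, 1]]]; b <- states[ns[tr$edge[e, 2]]]
      sample_branch_path(fit$Q, states, a, b, tr$edge.length[e],
                         P[ns[tr$edge[e, 1]], ns[tr$edge[e, 2]], e])
    })
    new_regime_painting(maps, states, node_states = states[ns], tree = tr)
  })
}
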