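#' Simulate a pure-birth tree scaled to unit height
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Optional integer seed; the same seed reproduces the same tree.
#' @param birth Speciation rate of the pure-birth process.
#' @return An ultrametric \code{ou_phylo} of unit height;
#'   \code{original_height} records the pre-scaling height.
#' @export
simulate_tree <- function(n_tips, seed = NULL, birth = 1) {
  stopifnot(n_tips >= 2)
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_tips, birth = birth, death = 0)
  scale_to_unit_height(as_ou_phylo(tr))
}

# preorder edge indices (parents before children)
preorder_edges <- function(tr) {
  rev(ape::reorder.phylo(tr, "postorder", index.only = TRUE))
}

#' Simulate Brownian motion on a tree
#'
#' Gaussian increments per branch with variance \code{sigma2 * length}.
#'
#' @param tr A tree.
#' @param sigma2 Diffusion variance per unit branch length (>= 0).
#' @param root Root value.
#' @param seed Optional seed.
#' @param n_rep Number of independent replicates (columns).
#' @param nodes If \code{TRUE} return values for all nodes, else tips only.
#' @return Matrix (tips-or-nodes x \code{n_rep}); a named vector when
#'   \code{n_rep = 1} and \code{nodes = FALSE}.
#' @export
simulate_bm <- function(tr, sigma2, root = 0, seed = NULL, n_rep = 1,
                        nodes = FALSE) {
  stopifnot(sigma2 >= 0)
  if (!is.null(seed)) set.seed(seed)
  ntip <- ape::Ntip(tr); nn <- ntip + tr$Nnode
  vals <- matrix(0, nn, n_rep)
  vals[ntip + 1L, ] <- root
  for (e in preorder_edges(tr)) {
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    vals[ch, ] <- vals[par, ] +
      stats::rnorm(n_rep, 0, sqrt(sigma2 * tr$edge.length[e]))
  }
  if (nodes) return(vals)
  out <- vals[seq_len(ntip), , drop = FALSE]
  rownames(out) <- tr$tip.label
  if (n_rep == 1) stats::setNames(out[, 1], tr$tip.label) else out
}

#' Simulate a discrete character (CTMC) on a tree
#'
#' Gillespie simulation along each branch from a root state drawn from the
#' stationary distribution of \code{Q}; returns both the tip data and the
#' true regime painting.
#'
#' @param tr A tree.
#' @param Q Rate matrix with state names as dimnames.
#' @param seed Optional seed.
#' @param root_state Optional fixed root state (default: stationary draw).
#' @return List with \code{tip_states}, \code{painting}
#'   (a \code{regime_painting}), and \code{node_states}.
#' @export
simulate_discrete <- function(tr, Q, seed = NULL, root_state = NULL) {
  states <- rownames(Q)
  if (is.null(states)) stop("Q needs state names as dimnames")
  if (!is.null(seed)) set.seed(seed)
  ntip <- ape::Ntip(tr); nn <- ntip + tr$Nnode
  node_states <- character(nn)
  node_states[ntip + 1L] <- if (!is.null(root_state)) root_state
    else sample(states, 1, prob = stationary_dist(Q))
  maps <- vector("list", nrow(tr$edge))
  for (e in preorder_edges(tr)) {
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    len <- tr$edge.length[e]
    cur <- node_states[par]
    t_at <- 0; segs <- numeric(0); labs <- character(0)
    repeat {
      rate <- -Q[cur, cur]
      dt <- if (rate > 0) stats::rexp(1, rate) else Inf
      if (t_at + dt >= len) {
        segs <- c(segs, len - t_at); labs <- c(labs, cur)
        break
      }
      segs <- c(segs, dt); labs <- c(labs, cur)
      t_at <- t_at + dt
      pr <- Q[cur, ]; pr[cur] <- 0
      cur <- sample(states, 1, prob = pr)
    }
    keep <- c(TRUE, labs[-1] != labs[-length(labs)])
    g <- cumsum(keep)
    m <- as.numeric(tapply(segs, g, sum)); names(m) <- labs[keep]
    maps[[e]] <- m
    node_states[ch] <- cur
  }
  p <- new_regime_painting(maps, states, node_states = node_states, tree = tr)
  list(tip_states = stats::setNames(node_states[seq_len(ntip)], tr$tip.label),
       painting = p, node_states = node_states)
}

#' Simulate the OU/trend response on a painted tree
#'
#' When the optimum depends only on the painted regime the process is
#' updated exactly segment by segment
#' (\code{u' = u e^(-a l) + theta_r (1 - e^(-a l)) + N(0, Vy (1 - e^(-2 a l)))},
#' trend variant \code{u' = u + tau_r l + N(0, Vy l)}), and a direct-effect
#' predictor \code{x} enters as \code{y = u + b x} so that the observed
#' slope on \code{x} is the unattenuated \code{b}. When the optimum tracks a
#' Brownian predictor \code{g}, \code{g} and the response are co-simulated
#' by fine-step Euler-Maruyama.
#'
#' @param tr A tree (unit height).
#' @param painting A \code{regime_painting} (or \code{NULL} for a single
#'   implicit regime named \code{"base"}).
#' @param config List: \code{t_half} (tree heights, \code{Inf} = trend),
#'   \code{vy} (> 0 stationary variance, or diffusion variance in the trend
#'   limit), \code{optima} or \code{trends} (named by regime), \code{root}
#'   (response root value), optional \code{b} (direct-effect slope),
#'   optional \code{g_slope} (optimal slope on the Brownian predictor; the
#'   trend variant interprets it as drift per unit predictor deviation),
#'   \code{g_sigma2}, \code{g_root}.
#' @param x Node-value matrix of the direct-effect predictor
#'   (\code{simulate_bm(..., nodes = TRUE)}), required when \code{b} is set.
#' @param n_rep Number of replicates.
#' @param seed Optional seed.
#' @param em_step Euler-Maruyama step in tree heights (default \code{1e-3});
#'   only used when \code{g_slope} is set.
#' @return List with \code{y} (tips x reps, or named vector for one rep)
#'   and, when co-simulated, \code{g} tips.
#' @export
simulate_response <- function(tr, painting, config, x = NULL, n_rep = 1,
                              seed = NULL, em_step = 1e-3) {
  if (!is.null(seed)) set.seed(seed)
  ntip <- ape::Ntip(tr); nn <- ntip + tr$Nnode
  trend <- is.infinite(config$t_half)
  a <- if (trend) 0 else log(2) / config$t_half
  vy <- config$vy
  theta <- if (trend) config$trends else config$optima
  use_g <- !is.null(config$g_slope)
  b <- config$b
  if (!is.null(b) && is.null(x)) stop("x node values required when b is set")
  if (is.null(painting)) {
    maps <- lapply(tr$edge.length, function(l) stats::setNames(l, "base"))
    painting <- new_regime_painting(maps, "base", tree = tr)
  }
  u <- matrix(0, nn, n_rep)
  u[ntip + 1L, ] <- config$root - if (!is.null(b)) b * x[ntip + 1L, ] else 0
  g <- NULL
  if (use_g) {
    g <- matrix(0, nn, n_rep)
    g[ntip + 1L, ] <- config$g_root
  }
  for (e in preorder_edges(tr)) {
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    uu <- u[par, ]
    gg <- if (use_g) g[par, ]
    m <- painting$maps[[e]]
    for (si in seq_along(m)) {
      l <- unname(m[si]); th <- theta[[names(m)[si]]]
      if (l <= 0) next
      if (!use_g) {
        if (trend) {
          uu <- uu + th * l + stats::rnorm(n_rep, 0, sqrt(vy * l))
        } else {
          w <- exp(-a * l)
          uu <- uu * w + th * (1 - w) +
            stats::rnorm(n_rep, 0, sqrt(vy * (1 - w^2)))
        }
      } else {
        nstep <- max(1L, ceiling(l / em_step))
        h <- l / nstep
        for (st in seq_len(nstep)) {
          gdev <- gg - config$g_root
          if (trend) {
            uu <- uu + (th + config$g_slope * gdev) * h +
              stats::rnorm(n_rep, 0, sqrt(vy * h))
          } else {
            uu <- uu - a * (uu - th - config$g_slope * gdev) * h +
              stats::rnorm(n_rep, 0, sqrt(2 * a * vy * h))
          }
          gg <- gg + stats::rnorm(n_rep, 0, sqrt(config$g_sigma2 * h))
        }
      }
    }
    u[ch, ] <- uu
    if (use_g) g[ch, ] <- gg
  }
  y <- u[seq_len(ntip), , drop = FALSE]
  if (!is.null(b)) y <- y + b * x[seq_len(ntip), , drop = FALSE]
  rownames(y) <- tr$tip.label
  out <- list(y = if (n_rep == 1) stats::setNames(y[, 1], tr$tip.label) else y)
  if (use_g) {
    gt <- g[seq_len(ntip), , drop = FALSE]
    rownames(gt) <- tr$tip.label
    out$g <- if (n_rep == 1) stats::setNames(gt[, 1], tr$tip.label) else gt
  }
  out
}

#' Add species-mean observation error
#'
#' Each species mean is observed as the average of \code{n_per_species}
#' measurements with within-species standard deviation \code{within_sd}; the
#' reported observation variance is the squared standard error
#' \code{within_sd^2 / n}.
#'
#' @param true_values Numeric vector of true species values.
#' @param n_per_species Integer sample sizes (>= 1, recycled).
#' @param within_sd Within-species SD (recycled).
#' @param seed Optional seed.
#' @return List with \code{observed} and \code{obs_var}.
#' @export
add_observation_error <- function(true_values, n_per_species, within_sd,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(true_values)
  m <- rep_len(n_per_species, n); sdw <- rep_len(within_sd, n)
  if (any(m < 1)) stop("n_per_species must be >= 1")
  se <- sdw / sqrt(m)
  obs <- true_values + stats::rnorm(n, 0, se)
  list(observed = stats::setNames(obs, names(true_values)),
       obs_var = stats::setNames(se^2, names(true_values)))
}

# Regime optima for the "primate" preset, chosen to have the magnitudes the
# published all-primates table reports (trends tau of order -8..3 per tree
# height at a half-life of 2.63, i.e. optima theta = tau/alpha). The
# unrealized folivory:polyandry combination gets the nonfolivorous value
# plus the average folivory offset.
.primate_optima <- function(alpha) {
  tau <- c("fol:harem" = -2.87, "fol:monog" = -1.70, "fol:polygynan" = 0.41,
           "fol:spatial" = -3.17, "nonfol:harem" = -4.19,
           "nonfol:monog" = -3.29, "nonfol:polyand" = -7.77,
           "nonfol:polygynan" = 3.25, "nonfol:spatial" = -1.32)
  shared <- c("harem", "monog", "polygynan", "spatial")
  off <- mean(tau[paste0("fol:", shared)] - tau[paste0("nonfol:", shared)])
  tau["fol:polyand"] <- tau["nonfol:polyand"] + off
  tau / alpha
}

#' Generate a study-like synthetic data set
#'
#' Emulates the structure of the 128-species comparative analysis: a
#' pure-birth unit-height tree; a 2-level diet factor, a 5-level
#' mating-system factor and a binary activity factor each evolving by an
#' equal-rates Markov chain; Brownian log body mass (about two decades of
#' range) and log group size; an OU response whose optimum depends on the
#' crossed diet-by-mating regime and on log group size, with a direct
#' body-mass effect; and species-mean observation error from per-species
#' sample sizes of 1-30.
#'
#' @param n_tips Number of species (default 128).
#' @param seed Integer seed (same seed, same bundle).
#' @param t_half,vy,b,g_evo_slope Core generating parameters; defaults are
#'   the published all-primates magnitudes (half-life 2.63 tree heights,
#'   stationary variance 0.18, direct slope 0.56, evolutionary group-size
#'   slope -0.04).
#' @return A \code{sim_bundle}: \code{tree}, \code{paintings} (diet,
#'   mating, activity, and the crossed diet_mating), \code{data} (a
#'   \code{species_table}), and \code{params} (the generating parameters,
#'   verbatim).
#' @export
generate_study_like <- function(n_tips = 128, seed = 1, t_half = 2.63,
                                vy = 0.18, b = 0.56, g_evo_slope = -0.04) {
  set.seed(seed)
  tr <- simulate_tree(n_tips)
  alpha <- log(2) / t_half
  rho <- rho_factor(alpha, 1)
  diet_Q <- build_Q(c("fol", "nonfol"), "ER", 0.5)
  mat_Q <- build_Q(c("harem", "monog", "polyand", "polygynan", "spatial"),
                   "ER", 0.5)
  act_Q <- build_Q(c("diurnal", "nocturnal"), "ER", 0.3)
  diet <- simulate_discrete(tr, diet_Q)
  mating <- simulate_discrete(tr, mat_Q)
  activity <- simulate_discrete(tr, act_Q)
  crossed <- cross_paintings(tr, diet$painting, mating$painting)
  x_nodes <- simulate_bm(tr, sigma2 = 2.25, root = log(5000), nodes = TRUE)
  params <- list(n_tips = n_tips, seed = seed, t_half = t_half, vy = vy,
                 b = b, g_evo_slope = g_evo_slope,
                 g_slope = g_evo_slope / rho, g_sigma2 = 1, g_root = log(8),
                 x_sigma2 = 2.25, x_root = log(5000), root = 3.4,
                 optima = .primate_optima(alpha),
                 diet_rate = 0.5, mating_rate = 0.5, activity_rate = 0.3,
                 within_sd_y = 0.15, within_sd_x = 0.2)
  cfg <- list(t_half = t_half, vy = vy, optima = params$optima, root = 3.4,
              b = b, g_slope = params$g_slope, g_sigma2 = 1, g_root = log(8))
  resp <- simulate_response(tr, crossed, cfg, x = x_nodes)
  nper_y <- sample(1:30, n_tips, replace = TRUE)
  nper_x <- sample(1:30, n_tips, replace = TRUE)
  ey <- add_observation_error(resp$y, nper_y, 0.15)
  ex <- add_observation_error(x_nodes[seq_len(n_tips), 1], nper_x, 0.2)
  df <- data.frame(
    species = tr$tip.label,
    log_ecv = unname(ey$observed), log_ecv_var = unname(ey$obs_var),
    log_body_mass = unname(ex$observed), log_body_mass_var = unname(ex$obs_var),
    log_group_size = unname(resp$g),
    group_size = exp(unname(resp$g)),
    diet = unname(diet$tip_states[tr$tip.label]),
    mating_system = unname(mating$tip_states[tr$tip.label]),
    activity_period = unname(activity$tip_states[tr$tip.label]),
    n_ecv = nper_y, n_body = nper_x,
    stringsAsFactors = FALSE)
  bundle <- list(tree = tr,
                 paintings = list(diet = diet$painting,
                                  mating_system = mating$painting,
                                  activity_period = activity$painting,
                                  diet_mating = crossed),
                 data = species_table(df, tree = tr),
                 params = params)
  class(bundle) <- "sim_bundle"
  bundle
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat("sim_bundle:", ape::Ntip(x$tree), "tips; t1/2 =", x$params$t_half,
      "Vy =", x$params$vy, "b =", x$params$b, "\n")
  invisible(x)
}

#' Write a simulation bundle to a directory
#'
#' Writes \code{tree.nwk}, \code{painting_<name>.nwk} (SIMMAP-annotated),
#' \code{data.csv}, \code{config.yaml} and \code{seed.txt}.
#'
#' @param bundle A \code{sim_bundle}.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory path.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ape::write.tree(bundle$tree, file.path(dir, "tree.nwk"))
  for (nm in names(bundle$paintings))
    write_simmap(bundle$tree, bundle$paintings[[nm]],
                 file.path(dir, paste0("painting_", nm, ".nwk")))
  utils::write.csv(bundle$data, file.path(dir, "data.csv"), row.names = FALSE)
  par <- bundle$params
  par$optima <- as.list(par$optima)
  yaml::write_yaml(par, file.path(dir, "config.yaml"))
  writeLines(as.character(bundle$params$seed), file.path(dir, "seed.txt"))
  invisible(dir)
}
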