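# Probabilistic inference on discrete Bayesian networks: exact
# enumeration (the oracle), likelihood weighting, and forward (logic)
# sampling with rejection.

#' Forward-sample complete records from a Bayesian network
#'
#' Ancestral sampling in topological order, vectorized over draws.
#'
#' @param net A \code{bn}.
#' @param n Number of records.
#' @param seed Optional RNG seed.
#' @return Data frame of factors, one column per node.
#' @export
rbn <- function(net, n, seed = NULL) {
  ord <- topo_order_or_null(net$dag)
  if (is.null(ord)) stop("network graph is cyclic")
  with_seed(seed, {
    out <- vector("list", length(ord)); names(out) <- ord
    idx <- list()
    nlev <- vapply(bn_levels(net), length, 1L)
    for (nd in ord) {
      cpt <- net$cpts[[nd]]
      cfg <- if (!length(cpt$parents)) rep(1L, n) else {
        i <- rep(0L, n); stride <- 1L
        for (p in cpt$parents) {
          i <- i + (idx[[p]] - 1L) * stride
          stride <- stride * nlev[[p]]
        }
        i + 1L
      }
      li <- sample_rows(cpt$prob, cfg)
      idx[[nd]] <- li
      out[[nd]] <- factor(cpt$levels[li], levels = cpt$levels)
    }
    as.data.frame(out, stringsAsFactors = FALSE)[net$dag$nodes]
  })
}

#' @noRd
check_evidence <- function(net, evidence) {
  lev <- bn_levels(net)
  for (nd in names(evidence)) {
    if (!nd %in% net$dag$nodes) stop(sprintf("evidence node '%s' not in network", nd))
    if (!evidence[[nd]] %in% lev[[nd]]) {
      stop(sprintf("'%s' is not a level of node '%s'", evidence[[nd]], nd))
    }
  }
  invisible(TRUE)
}

#' Full joint distribution by enumeration (internal)
#'
#' Returns level-index matrix of all joint states and their probabilities.
#' Guarded to small state spaces.
#' @noRd
joint_enumeration <- function(net, max_states = 2^20) {
  lev <- bn_levels(net)
  nlev <- vapply(lev, length, 1L)
  M <- prod(nlev)
  if (M > max_states) stop(sprintf("state space too large for enumeration (%g states)", M))
  nodes <- net$dag$nodes
  states <- matrix(0L, M, length(nodes), dimnames = list(NULL, nodes))
  stride <- 1
  for (nd in nodes) {
    states[, nd] <- ((seq_len(M) - 1L) %/% stride) %% nlev[[nd]] + 1L
    stride <- stride * nlev[[nd]]
  }
  p <- rep(1, M)
  for (nd in nodes) {
    cpt <- net$cpts[[nd]]
    cfg <- if (!length(cpt$parents)) rep(1L, M) else {
      i <- rep(0L, M); s <- 1L
      for (pa in cpt$parents) { i <- i + (states[, pa] - 1L) * s; s <- s * nlev[[pa]] }
      i + 1L
    }
    p <- p * cpt$prob[cbind(cfg, states[, nd])]
  }
  list(states = states, prob = p)
}

#' Exact posterior by full-joint enumeration
#'
#' The reference engine for the sampling algorithms: enumerates the joint
#' distribution, conditions on the evidence and renormalizes.
#'
#' @param net A \code{bn}.
#' @param evidence Named list/vector mapping nodes to observed levels
#'   (may be empty).
#' @param query Query node name.
#' @param joint Optional precomputed result of the internal enumeration,
#'   for repeated queries on one network.
#' @return Named probability vector over the query node's levels.
#' @export
infer_exact <- function(net, evidence = list(), query, joint = NULL) {
  check_evidence(net, evidence)
  if (is.null(joint)) joint <- joint_enumeration(net)
  lev <- bn_levels(net)
  keep <- rep(TRUE, length(joint$prob))
  for (nd in names(evidence)) {
    keep <- keep & joint$states[, nd] == match(evidence[[nd]], lev[[nd]])
  }
  w <- joint$prob[keep]
  if (sum(w) <= 0) stop("impossible evidence: zero prior probability")
  qs <- joint$states[keep, query]
  p <- vapply(seq_along(lev[[query]]), function(l) sum(w[qs == l]), 0)
  stats::setNames(p / sum(p), lev[[query]])
}

#' Posterior by likelihood weighting
#'
#' Samples non-evidence nodes topologically, clamps evidence nodes and
#' weights each sample by the product of the evidence likelihoods given
#' the sampled parents. Lower variance than rejection-style logic
#' sampling when the evidence is unlikely.
#'
#' @param net A \code{bn}.
#' @param evidence Named list of observed levels (may be empty, in which
#'   case the estimator reduces to forward sampling with unit weights).
#' @param query Query node.
#' @param n_samples Number of weighted samples.
#' @param seed Optional RNG seed.
#' @return List with \code{prob} (named vector), \code{se} (Monte Carlo
#'   standard errors, ratio-estimator form) and \code{ess} (effective
#'   sample size of the weights).
#' @export
infer_lw <- function(net, evidence = list(), query, n_samples = 10000L, seed = NULL) {
  stopifnot(n_samples >= 1L)
  check_evidence(net, evidence)
  ord <- topo_order_or_null(net$dag)
  lev <- bn_levels(net)
  nlev <- vapply(lev, length, 1L)
  with_seed(seed, {
    idx <- list()
    w <- rep(1, n_samples)
    for (nd in ord) {
      cpt <- net$cpts[[nd]]
      cfg <- if (!length(cpt$parents)) rep(1L, n_samples) else {
        i <- rep(0L, n_samples); s <- 1L
        for (pa in cpt$parents) { i <- i + (idx[[pa]] - 1L) * s; s <- s * nlev[[pa]] }
        i + 1L
      }
      if (nd %in% names(evidence)) {
        li <- rep(match(evidence[[nd]], lev[[nd]]), n_samples)
        w <- w * cpt$prob[cbind(cfg, li)]
      } else {
        li <- sample_rows(cpt$prob, cfg)
      }
      idx[[nd]] <- li
    }
    W <- sum(w)
    if (W <= 0) stop("evidence unreachable: all likelihood weights are zero")
    qs <- idx[[query]]
    L <- nlev[[query]]
    p <- vapply(seq_len(L), function(l) sum(w[qs == l]), 0) / W
    # ratio-estimator standard error per level
    se <- vapply(seq_len(L), function(l) {
      sqrt(sum((w * ((qs == l) - p[l]))^2)) / W
    }, 0)
    list(prob = stats::setNames(p, lev[[query]]),
         se = stats::setNames(se, lev[[query]]),
         ess = W^2 / sum(w^2))
  })
}

#' Posterior by logic (forward rejection) sampling
#'
#' Ancestral sampling of all nodes with rejection of draws inconsistent
#' with the evidence.
#'
#' @inheritParams infer_lw
#' @return List with \code{prob}, \code{n_accepted} and
#'   \code{acceptance_rate}.
#' @export
infer_logic_sampling <- function(net, evidence = list(), query,
                                 n_samples = 10000L, seed = NULL) {
  stopifnot(n_samples >= 1L)
  check_evidence(net, evidence)
  draws <- rbn(net, n_samples, seed = seed)
  keep <- rep(TRUE, n_samples)
  for (nd in names(evidence)) keep <- keep & draws[[nd]] == evidence[[nd]]
  n_acc <- sum(keep)
  if (n_acc == 0L) {
    stop(sprintf("no samples consistent with evidence (acceptance rate 0/%d)", n_samples))
  }
  tab <- table(draws[[query]][keep])
  list(prob = stats::setNames(as.vector(tab) / n_acc, names(tab)),
       n_accepted = n_acc, acceptance_rate = n_acc / n_samples)
}

#' Batch posterior of one query node under alternative evidence scenarios
#'
#' Evaluates each evidence set with a shared seed (so scenarios differ
#' only in their evidence) and reports the posterior alongside its delta
#' against the no-evidence marginal. Used for the counterfactual-style
#' "abnormal labs vs corrected labs" readouts.
#'
#' @param net A \code{bn}.
#' @param evidence_sets Named list of evidence lists.
#' @param query Query node (default \code{"aki"}).
#' @param level Query level whose posterior is reported (default second
#'   level, i.e. "yes"/TRUE for binary nodes).
#' @param n_samples,seed Passed to \code{\link{infer_lw}}.
#' @param engine \code{"lw"} (default) or \code{"exact"}.
#' @return Data frame: scenario, posterior, marginal, delta.
#' @export
scenario_inference <- function(net, evidence_sets, query = "aki", level = NULL,
                               n_samples = 50000L, seed = NULL, engine = c("lw", "exact")) {
  engine <- match.arg(engine)
  lev <- bn_levels(net)[[query]]
  if (is.null(level)) level <- lev[min(2L, length(lev))]
  post_of <- function(ev) {
    if (engine == "exact") infer_exact(net, ev, query)[[level]]
    else infer_lw(net, ev, query, n_samples = n_samples, seed = seed)$prob[[level]]
  }
  marg <- post_of(list())
  if (is.null(names(evidence_sets))) {
    names(evidence_sets) <- paste0("scenario_", seq_along(evidence_sets))
  }
  post <- vapply(evidence_sets, post_of, 0)
  data.frame(scenario = names(evidence_sets), posterior = unname(post),
             marginal = marg, delta = unname(post) - marg,
             stringsAsFactors = FALSE)
}
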