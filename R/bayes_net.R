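# Discrete Bayesian networks: DAG + CPT containers, decomposable BIC
# scoring, and score-based structure learning by tabu search.

#' Construct a directed acyclic graph over named categorical nodes
#'
#' @param nodes Character vector of node names.
#' @param arcs Two-column matrix or data.frame of arcs (from, to); may be
#'   \code{NULL} for the empty graph.
#' @return An object of class \code{bn_dag} with fields \code{nodes} and
#'   \code{parents} (named list, one character vector per node).
#' @export
bn_dag <- function(nodes, arcs = NULL) {
  stopifnot(is.character(nodes), !anyDuplicated(nodes))
  parents <- stats::setNames(vector("list", length(nodes)), nodes)
  for (nd in nodes) parents[[nd]] <- character(0)
  if (!is.null(arcs) && NROW(arcs) > 0) {
    arcs <- as.matrix(arcs)
    if (ncol(arcs) != 2) stop("arcs must have two columns (from, to)")
    if (!all(arcs %in% nodes)) stop("arc endpoints must be nodes")
    if (any(arcs[, 1] == arcs[, 2])) stop("self-loops are not allowed")
    for (i in seq_len(nrow(arcs))) {
      parents[[arcs[i, 2]]] <- union(parents[[arcs[i, 2]]], arcs[i, 1])
    }
  }
  dag <- structure(list(nodes = nodes, parents = parents), class = "bn_dag")
  if (dag_has_cycle(dag)) stop("arcs induce a directed cycle")
  dag
}

#' Arcs of a DAG as a two-column (from, to) matrix
#' @param dag A \code{bn_dag}.
#' @return Character matrix with columns \code{from}, \code{to}.
#' @export
dag_arcs <- function(dag) {
  out <- NULL
  for (nd in dag$nodes) {
    for (p in dag$parents[[nd]]) out <- rbind(out, c(p, nd))
  }
  if (is.null(out)) out <- matrix(character(0), 0, 2)
  colnames(out) <- c("from", "to")
  out
}

#' @noRd
dag_has_cycle <- function(dag) {
  is.null(topo_order_or_null(dag))
}

#' Topological order of a DAG (Kahn's algorithm), NULL if cyclic
#' @noRd
topo_order_or_null <- function(dag) {
  indeg <- vapply(dag$parents, length, 1L)
  order <- character(0)
  avail <- names(indeg)[indeg == 0L]
  indeg2 <- indeg
  while (length(avail)) {
    nd <- sort(avail)[1L]  # deterministic
    avail <- setdiff(avail, nd)
    order <- c(order, nd)
    for (ch in dag$nodes) {
      if (nd %in% dag$parents[[ch]]) {
        indeg2[[ch]] <- indeg2[[ch]] - 1L
        if (indeg2[[ch]] == 0L && !(ch %in% order)) avail <- union(avail, ch)
      }
    }
  }
  if (length(order) == length(dag$nodes)) order else NULL
}

#' TRUE if a directed path from `from` to `to` exists
#' @noRd
dag_path_exists <- function(dag, from, to) {
  if (from == to) return(TRUE)
  children <- function(nd) dag$nodes[vapply(dag$nodes, function(ch) nd %in% dag$parents[[ch]], TRUE)]
  seen <- character(0)
  frontier <- from
  while (length(frontier)) {
    nxt <- unique(unlist(lapply(frontier, children)))
    if (to %in% nxt) return(TRUE)
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
    frontier <- nxt
  }
  FALSE
}

#' Conditional probability table for one node
#'
#' Rows index joint parent configurations (first parent varying fastest,
#' the `expand.grid` convention); columns index the node's levels.
#'
#' @param node Node name.
#' @param levels Character vector of the node's levels.
#' @param parents Character vector of parent names (possibly empty).
#' @param parent_levels Named list of level sets for the parents.
#' @param prob Numeric matrix (configurations x levels); each row must sum
#'   to 1. A vector is accepted for a parentless node.
#' @param counts Optional matrix of observation counts backing `prob`.
#' @return Object of class \code{bn_cpt}.
#' @export
bn_cpt <- function(node, levels, parents = character(0),
                   parent_levels = list(), prob, counts = NULL) {
  if (is.vector(prob)) prob <- matrix(prob, nrow = 1L)
  n_cfg <- if (length(parents)) prod(vapply(parent_levels[parents], length, 1L)) else 1L
  if (nrow(prob) != n_cfg || ncol(prob) != length(levels)) {
    stop(sprintf("CPT for '%s' must be %d x %d", node, n_cfg, length(levels)))
  }
  for (i in seq_len(nrow(prob))) check_prob_row(prob[i, ], node)
  colnames(prob) <- levels
  structure(list(node = node, levels = levels, parents = parents,
                 parent_levels = parent_levels[parents], prob = prob,
                 counts = counts),
            class = "bn_cpt")
}

#' Assemble a Bayesian network from a DAG and one CPT per node
#'
#' @param dag A \code{bn_dag}.
#' @param cpts Named list of \code{bn_cpt}, one per node; parent sets must
#'   match the DAG.
#' @return Object of class \code{bn}.
#' @export
bayes_net <- function(dag, cpts) {
  stopifnot(inherits(dag, "bn_dag"))
  if (!setequal(names(cpts), dag$nodes)) stop("cpts must cover exactly the DAG nodes")
  for (nd in dag$nodes) {
    if (!setequal(cpts[[nd]]$parents, dag$parents[[nd]])) {
      stop(sprintf("CPT parents for '%s' do not match the DAG", nd))
    }
  }
  structure(list(dag = dag, cpts = cpts[dag$nodes]), class = "bn")
}

#' @export
print.bn <- function(x, ...) {
  arcs <- dag_arcs(x$dag)
  cat(sprintf("Discrete Bayesian network: %d nodes, %d arcs\n",
              length(x$dag$nodes), nrow(arcs)))
  for (nd in x$dag$nodes) {
    p <- x$dag$parents[[nd]]
    cat(sprintf("  %s (%d levels)%s\n", nd, length(x$cpts[[nd]]$levels),
                if (length(p)) paste0(" <- ", paste(p, collapse = ", ")) else ""))
  }
  invisible(x)
}

#' Node levels of a network, as a named list
#' @noRd
bn_levels <- function(net) lapply(net$cpts, `[[`, "levels")

# ---- data preparation ------------------------------------------------------

#' Integer-code a categorical data frame for scoring/fitting
#'
#' Complete cases on `nodes` only; factor levels are taken from the data's
#' factor levels (or sorted unique values for character columns).
#' @noRd
bn_data_matrix <- function(data, nodes, levels = NULL) {
  miss <- setdiff(nodes, names(data))
  if (length(miss)) stop(sprintf("node(s) absent from data: %s", paste(miss, collapse = ", ")))
  df <- data[, nodes, drop = FALSE]
  keep <- stats::complete.cases(df)
  df <- df[keep, , drop = FALSE]
  lev <- vector("list", length(nodes)); names(lev) <- nodes
  m <- matrix(0L, nrow(df), length(nodes), dimnames = list(NULL, nodes))
  for (nd in nodes) {
    x <- df[[nd]]
    if (is.logical(x)) x <- factor(x, levels = c(FALSE, TRUE))
    if (!is.factor(x)) x <- factor(x)
    if (!is.null(levels) && !is.null(levels[[nd]])) x <- factor(as.character(x), levels = levels[[nd]])
    lev[[nd]] <- base::levels(x)
    m[, nd] <- as.integer(x)
  }
  if (anyNA(m)) stop("level mismatch while coding data")
  list(m = m, levels = lev, n = nrow(m))
}

#' Parent-configuration index (1-based, first parent fastest)
#' @noRd
config_index <- function(m, parents, nlev) {
  if (!length(parents)) return(rep(1L, nrow(m)))
  idx <- rep(0L, nrow(m)); stride <- 1L
  for (p in parents) {
    idx <- idx + (m[, p] - 1L) * stride
    stride <- stride * nlev[[p]]
  }
  idx + 1L
}

#' Multinomial log-likelihood of one node given its parents
#' @noRd
family_loglik <- function(bd, node, parents) {
  nlev <- vapply(bd$levels, length, 1L)
  cfg <- config_index(bd$m, parents, nlev)
  L <- nlev[[node]]
  ncfg <- if (length(parents)) prod(nlev[parents]) else 1L
  counts <- tabulate(bd$m[, node] + (cfg - 1L) * L, nbins = L * ncfg)
  counts <- matrix(counts, nrow = ncfg, byrow = TRUE)
  rowtot <- rowSums(counts)
  nz <- counts > 0
  ll <- sum(counts[nz] * log(counts[nz] / rowtot[row(counts)[nz]]))
  list(loglik = ll, counts = counts, d = (L - 1L) * ncfg)
}

# ---- BIC score -------------------------------------------------------------

#' BIC score of a DAG against categorical data
#'
#' Decomposable network score: for each node,
#' \eqn{LL_i - (d_i/2)\log N}, where \eqn{LL_i} is the multinomial
#' log-likelihood of the node given its parents and
#' \eqn{d_i = (L_i - 1) \prod_{p} L_p} its free-parameter count. Complete
#' cases on the DAG's nodes are used.
#'
#' @param dag A \code{bn_dag}.
#' @param data Data frame of categorical columns covering the DAG nodes.
#' @return List with \code{score} (total) and \code{by_node} (named vector).
#' @export
bic_score <- function(dag, data) {
  bd <- bn_data_matrix(data, dag$nodes)
  by_node <- vapply(dag$nodes, function(nd) {
    fam <- family_loglik(bd, nd, dag$parents[[nd]])
    fam$loglik - fam$d / 2 * log(bd$n)
  }, 0)
  list(score = sum(by_node), by_node = by_node)
}

# ---- tabu search -----------------------------------------------------------

#' Learn a DAG by BIC-scored tabu search
#'
#' Greedy search over single-arc moves (add, delete, reverse) maximizing
#' the decomposable BIC score, with a tabu list of recently applied moves
#' to escape local optima. Ties between equal-score moves are broken by
#' lexicographic arc order, so the search is deterministic (the \code{seed}
#' only matters when \code{restarts > 0}).
#'
#' @param data Data frame of categorical columns.
#' @param nodes Columns to model; defaults to all columns.
#' @param tabu_len Length of the tabu list.
#' @param max_iter Iteration cap.
#' @param stall Stop after this many consecutive non-improving moves.
#' @param restarts Number of random restarts (perturb the best DAG).
#' @param seed RNG seed used only for restarts.
#' @param whitelist Two-column matrix of arcs forced present.
#' @param blacklist Two-column matrix of arcs never added.
#' @param max_parents Cap on the in-degree of any node.
#' @return The best-scoring \code{bn_dag} found, with the score in
#'   attribute \code{"score"}.
#' @export
tabu_learn <- function(data, nodes = NULL, tabu_len = 10L, max_iter = 10000L,
                       stall = NULL, restarts = 0L, seed = NULL,
                       whitelist = NULL, blacklist = NULL, max_parents = 8L) {
  if (is.null(nodes)) nodes <- names(data)
  if (length(nodes) < 2L) stop("need at least two variables")
  bd <- bn_data_matrix(data, nodes)
  if (is.null(stall)) stall <- max(tabu_len, 10L)
  nlev <- vapply(bd$levels, length, 1L)
  npar_heur <- 5L * sum(nlev - 1L)
  if (bd$n < npar_heur) {
    message(sprintf("note: %d complete cases < 5x parameter heuristic (%d)", bd$n, npar_heur))
  }

  black <- if (is.null(blacklist)) matrix(character(0), 0, 2) else as.matrix(blacklist)
  white <- if (is.null(whitelist)) matrix(character(0), 0, 2) else as.matrix(whitelist)
  is_black <- function(f, t) any(black[, 1] == f & black[, 2] == t)
  is_white <- function(f, t) any(white[, 1] == f & white[, 2] == t)

  # local score cache keyed by node + sorted parent set
  cache <- new.env(parent = emptyenv())
  local_score <- function(node, parents) {
    key <- paste(node, paste(sort(parents), collapse = ","), sep = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    fam <- family_loglik(bd, node, parents)
    s <- fam$loglik - fam$d / 2 * log(bd$n)
    cache[[key]] <- s
    s
  }

  start_dag <- bn_dag(nodes, if (nrow(white)) white else NULL)
  if (nrow(white) && dag_has_cycle(start_dag)) stop("whitelist induces a cycle")

  search_from <- function(dag) {
    score_by <- vapply(nodes, function(nd) local_score(nd, dag$parents[[nd]]), 0)
    best_dag <- dag; best_score <- sum(score_by)
    tabu <- character(0)
    cur <- dag; cur_score <- best_score
    no_improve <- 0L
    for (iter in seq_len(max_iter)) {
      moves <- list()
      for (f in nodes) for (t in nodes) {
        if (f == t) next
        has_arc <- f %in% cur$parents[[t]]
        if (!has_arc) {
          # add f -> t
          if (is_black(f, t)) next
          if (length(cur$parents[[t]]) >= max_parents) next
          if (dag_path_exists(cur, t, f)) next  # would create a cycle
          delta <- local_score(t, c(cur$parents[[t]], f)) - score_by[[t]]
          moves[[length(moves) + 1L]] <- list(op = "add", from = f, to = t, delta = delta)
        } else {
          if (!is_white(f, t)) {
            delta <- local_score(t, setdiff(cur$parents[[t]], f)) - score_by[[t]]
            moves[[length(moves) + 1L]] <- list(op = "del", from = f, to = t, delta = delta)
            # reverse f -> t
            if (!is_black(t, f) && length(cur$parents[[f]]) < max_parents) {
              tmp <- cur
              tmp$parents[[t]] <- setdiff(tmp$parents[[t]], f)
              if (!dag_path_exists(tmp, f, t)) {
                delta_r <- (local_score(t, setdiff(cur$parents[[t]], f)) - score_by[[t]]) +
                  (local_score(f, c(cur$parents[[f]], t)) - score_by[[f]])
                moves[[length(moves) + 1L]] <- list(op = "rev", from = f, to = t, delta = delta_r)
              }
            }
          }
        }
      }
      if (!length(moves)) break
      keys <- vapply(moves, function(mv) paste(mv$op, mv$from, mv$to), "")
      deltas <- vapply(moves, `[[`, 0, "delta")
      ord <- order(-deltas, keys)  # best delta, lexicographic tie-break
      chosen <- NULL
      for (i in ord) {
        mv <- moves[[i]]
        # tabu unless aspiration (strictly beats best seen)
        inv_key <- switch(mv$op,
                          add = paste("del", mv$from, mv$to),
                          del = paste("add", mv$from, mv$to),
                          rev = paste("rev", mv$to, mv$from))
        if ((keys[i] %in% tabu || inv_key %in% tabu) &&
            cur_score + mv$delta <= best_score + 1e-12) next
        chosen <- mv
        break
      }
      if (is.null(chosen)) break
      # apply
      if (chosen$op == "add") {
        cur$parents[[chosen$to]] <- c(cur$parents[[chosen$to]], chosen$from)
        score_by[[chosen$to]] <- local_score(chosen$to, cur$parents[[chosen$to]])
      } else if (chosen$op == "del") {
        cur$parents[[chosen$to]] <- setdiff(cur$parents[[chosen$to]], chosen$from)
        score_by[[chosen$to]] <- local_score(chosen$to, cur$parents[[chosen$to]])
      } else {
        cur$parents[[chosen$to]] <- setdiff(cur$parents[[chosen$to]], chosen$from)
        cur$parents[[chosen$from]] <- c(cur$parents[[chosen$from]], chosen$to)
        score_by[[chosen$to]] <- local_score(chosen$to, cur$parents[[chosen$to]])
        score_by[[chosen$from]] <- local_score(chosen$from, cur$parents[[chosen$from]])
      }
      cur_score <- sum(score_by)
      tabu <- c(paste(chosen$op, chosen$from, chosen$to), tabu)
      if (length(tabu) > tabu_len) tabu <- tabu[seq_len(tabu_len)]
      if (cur_score > best_score + 1e-12) {
        best_score <- cur_score; best_dag <- cur; no_improve <- 0L
      } else {
        no_improve <- no_improve + 1L
        if (no_improve >= stall) break
      }
    }
    list(dag = best_dag, score = best_score)
  }

  best <- search_from(start_dag)
  if (restarts > 0L) {
    with_seed(if (is.null(seed)) 1L else seed, {
      for (r in seq_len(restarts)) {
        pert <- best$dag
        arcs <- dag_arcs(pert)
        if (nrow(arcs)) {
          drop <- sample(nrow(arcs), size = min(2L, nrow(arcs)))
          for (i in drop) {
            if (is_white(arcs[i, 1], arcs[i, 2])) next
            pert$parents[[arcs[i, 2]]] <- setdiff(pert$parents[[arcs[i, 2]]], arcs[i, 1])
          }
        }
        cand <- search_from(pert)
        if (cand$score > best$score) best <- cand
      }
    })
  }
  structure(best$dag, score = best$score)
}

# ---- parameter learning ----------------------------------------------------

#' Fit conditional probability tables by maximum likelihood
#'
#' Each CPT row is the relative frequency of the node's levels within one
#' joint parent configuration, optionally with a pseudo-count added to
#' every cell. Parent configurations never observed fall back to the
#' uniform distribution (with a warning) so inference never meets an
#' all-zero row.
#'
#' @param dag A \code{bn_dag}.
#' @param data Data frame of categorical columns.
#' @param smoothing Pseudo-count added to every cell (>= 0).
#' @param levels Optional named list fixing the level sets.
#' @return A \code{bn} object.
#' @export
fit_cpts <- function(dag, data, smoothing = 0, levels = NULL) {
  stopifnot(smoothing >= 0)
  bd <- bn_data_matrix(data, dag$nodes, levels = levels)
  nlev <- vapply(bd$levels, length, 1L)
  cpts <- list()
  for (nd in dag$nodes) {
    fam <- family_loglik(bd, nd, dag$parents[[nd]])
    counts <- fam$counts + smoothing
    rowtot <- rowSums(counts)
    zero <- rowtot == 0
    if (any(zero)) {
      warning(sprintf("node '%s': %d unobserved parent configuration(s), using uniform rows",
                      nd, sum(zero)))
      counts[zero, ] <- 1
      rowtot <- rowSums(counts)
    }
    prob <- counts / rowtot
    cpts[[nd]] <- bn_cpt(nd, bd$levels[[nd]], dag$parents[[nd]],
                         bd$levels, prob, counts = fam$counts)
  }
  bayes_net(dag, cpts)
}

#' Formatted conditional probability table for one node
#'
#' Returns the node's CPT as a data frame with one column per parent and
#' one percentage column per node level, rows ordered with the first
#' parent varying slowest (the layout used for clinical CPD tables: e.g.
#' eGFR band x hemoglobin band x sodium band against AKI yes/no).
#'
#' @param net A \code{bn}.
#' @param node Node name.
#' @return Data frame; percentage columns are named \code{pct_<level>}.
#' @export
cpd_table <- function(net, node) {
  cpt <- net$cpts[[node]]
  if (is.null(cpt)) stop(sprintf("no node '%s' in network", node))
  if (!length(cpt$parents)) {
    out <- as.data.frame(as.list(100 * cpt$prob[1L, ]))
    names(out) <- paste0("pct_", cpt$levels)
    return(out)
  }
  grid <- do.call(expand.grid, c(cpt$parent_levels, stringsAsFactors = FALSE))
  pct <- 100 * cpt$prob
  colnames(pct) <- paste0("pct_", cpt$levels)
  out <- cbind(grid, as.data.frame(pct))
  # first parent slowest for display
  ord <- do.call(order, lapply(names(grid), function(p) match(grid[[p]], cpt$parent_levels[[p]])))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
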