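# Shared test fixtures: random networks, random creatinine series, an
# independent brute-force KDIGO oracle, and skeleton utilities.

# Random discrete network with 2-3 levels per node and Dirichlet-ish CPTs.
rand_net <- function(n_nodes, seed, p_arc = 0.4) {
  withr::with_seed(seed, {
    nodes <- paste0("X", seq_len(n_nodes))
    arcs <- NULL
    for (j in seq_len(n_nodes)) {
      for (i in seq_len(j - 1)) {
        if (stats::runif(1) < p_arc) arcs <- rbind(arcs, c(nodes[i], nodes[j]))
      }
    }
    dag <- bn_dag(nodes, arcs)
    lev <- lapply(nodes, function(nd) paste0("l", seq_len(sample(2:3, 1))))
    names(lev) <- nodes
    cpts <- lapply(nodes, function(nd) {
      pa <- dag$parents[[nd]]
      ncfg <- if (length(pa)) prod(vapply(lev[pa], length, 1L)) else 1L
      pm <- matrix(stats::rgamma(ncfg * length(lev[[nd]]), 1.5) + 0.05, ncfg)
      bn_cpt(nd, lev[[nd]], pa, lev, pm / rowSums(pm))
    })
    names(cpts) <- nodes
    bayes_net(dag, cpts)
  })
}

# Random SCr series: 2-8 measurements over up to 10 days, values spanning
# the plausible clinical range so both KDIGO clauses get exercised.
rand_scr_series <- function(seed) {
  withr::with_seed(seed, {
    m <- sample(2:8, 1)
    t <- sort(stats::runif(m, 0, 240))
    while (any(diff(t) <= 0.1)) t <- sort(stats::runif(m, 0, 240))
    s <- stats::runif(m, 30, 260)
    data.frame(time_hours = t, scr = s)
  })
}

# Independent exhaustive KDIGO oracle: O(m^2) over all measurement pairs,
# coded separately from the package implementation.
oracle_detect_aki <- function(series) {
  t <- series$time_hours; s <- series$scr
  m <- length(t)
  aki <- FALSE; stage <- 0L
  best_fold <- 0
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      dt <- t[j] - t[i]
      if (dt <= 48 && s[j] - s[i] >= 26.5) { aki <- TRUE; stage <- max(stage, 1L) }
      if (dt <= 168) {
        f <- s[j] / s[i]
        best_fold <- max(best_fold, f)
        if (f >= 1.5) aki <- TRUE
      }
    }
  }
  if (best_fold >= 3.0) stage <- 3L
  else if (best_fold >= 2.0) stage <- max(stage, 2L)
  else if (best_fold >= 1.5) stage <- max(stage, 1L)
  if (aki && max(s) >= 353.6) stage <- 3L
  list(has_aki = aki, stage = stage)
}

# Undirected skeleton of an arc matrix, as a canonical string set.
skel_set <- function(arcs) {
  if (NROW(arcs) == 0) return(character(0))
  unique(apply(arcs, 1, function(a) paste(sort(a), collapse = "~")))
}

shd_skeleton <- function(dag, truth_arcs) {
  a <- skel_set(dag_arcs(dag)); b <- skel_set(truth_arcs)
  length(setdiff(a, b)) + length(setdiff(b, a))
}

truth_arc_matrix <- function() {
  rbind(c("hm_category", "hemoglobin_low"), c("hm_category", "egfr_band"),
        c("diabetes", "egfr_band"), c("age_band", "aki"),
        c("hemoglobin_low", "aki"), c("egfr_band", "aki"),
        c("sodium_band", "aki"), c("potassium_band", "aki"))
}

truth_nodes <- function() {
  c("age_band", "diabetes", "hm_category", "sodium_band", "potassium_band",
    "hemoglobin_low", "egfr_band", "aki")
}

# Small coded cohort, memoised per (n, seed) within a test run.
.coded_cache <- new.env(parent = emptyenv())
coded_cohort_fixture <- function(n = 1500, seed = 11) {
  key <- paste(n, seed)
  if (is.null(.coded_cache[[key]])) {
    co <- simulate_cohort(cohort_params(n_patients = n), seed = seed)
    .coded_cache[[key]] <- list(
      coded = code_cohort(apply_eligibility(co)$eligible),
      truth = attr(co, "truth"))
  }
  .coded_cache[[key]]
}
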