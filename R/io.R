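# Readers and writers for the pipeline's artifact formats: cohort CSVs
# (patient table + long-format SCr series), the coded analysis table
# with its JSON data dictionary, and network serializations (canonical
# JSON and BIF).

#' Write a cohort to CSV (patient table + SCr series)
#'
#' One row per patient with labs as columns; the serum-creatinine
#' series goes to a separate long-format file (patient_id, time_hours,
#' scr). UTF-8, comma separator, missing values as empty cells.
#'
#' @param cohort An \code{aki_cohort}.
#' @param patients_path,scr_path Output paths.
#' @export
write_cohort_csv <- function(cohort, patients_path, scr_path) {
  lab_names <- c("alt", "ast", "tbil", "scr", "egfr", "sua", "albumin",
                 "hemoglobin", "wbc", "sodium", "potassium")
  rows <- lapply(cohort, function(p) {
    labs <- lapply(lab_names, function(l) {
      v <- p$labs[[l]]; if (is.null(v)) NA_real_ else as.numeric(v)
    })
    names(labs) <- paste0("lab_", lab_names)
    c(list(patient_id = p$patient_id, age_years = p$age_years, gender = p$gender,
           hypertension = p$hypertension, diabetes = p$diabetes,
           hm_category = p$hm_category, admission_type = p$admission_type,
           treatment = p$treatment,
           dialysis_or_rrt_at_baseline = p$dialysis_or_rrt_at_baseline,
           los_hours = p$los_hours), labs)
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  utils::write.csv(df, patients_path, row.names = FALSE, na = "")
  scr <- do.call(rbind, lapply(cohort, function(p) {
    data.frame(patient_id = p$patient_id, time_hours = p$scr_series$time_hours,
               scr = p$scr_series$scr, stringsAsFactors = FALSE)
  }))
  utils::write.csv(scr, scr_path, row.names = FALSE, na = "")
  invisible(c(patients_path, scr_path))
}

#' Read a cohort written by \code{\link{write_cohort_csv}}
#' @param patients_path,scr_path Input paths.
#' @return An \code{aki_cohort}.
#' @export
read_cohort_csv <- function(patients_path, scr_path) {
  df <- utils::read.csv(patients_path, stringsAsFactors = FALSE)
  scr <- utils::read.csv(scr_path, stringsAsFactors = FALSE)
  lab_cols <- grep("^lab_", names(df), value = TRUE)
  records <- lapply(seq_len(nrow(df)), function(i) {
    labs <- as.list(df[i, lab_cols])
    names(labs) <- sub("^lab_", "", lab_cols)
    s <- scr[scr$patient_id == df$patient_id[i], c("time_hours", "scr")]
    structure(list(
      patient_id = df$patient_id[i], age_years = df$age_years[i],
      gender = df$gender[i], hypertension = df$hypertension[i],
      diabetes = df$diabetes[i], hm_category = df$hm_category[i],
      admission_type = df$admission_type[i], treatment = df$treatment[i],
      dialysis_or_rrt_at_baseline = df$dialysis_or_rrt_at_baseline[i],
      labs = labs, scr_series = s[order(s$time_hours), , drop = FALSE],
      los_hours = df$los_hours[i]), class = "patient_record")
  })
  structure(records, class = "aki_cohort")
}

#' Write the coded analysis table plus its JSON data dictionary
#' @param coded A \code{coded_cohort}.
#' @param path CSV output path; the dictionary goes to
#'   \code{<path>.dict.json}.
#' @export
write_coded_csv <- function(coded, path) {
  utils::write.csv(as.data.frame(coded), path, row.names = FALSE, na = "")
  jsonlite::write_json(coding_dictionary(), paste0(path, ".dict.json"),
                       dataframe = "rows", auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a coded analysis table from CSV
#' @param path CSV path written by \code{\link{write_coded_csv}}.
#' @return A \code{coded_cohort}.
#' @export
read_coded_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  for (v in intersect(names(aki_levels), names(df))) {
    df[[v]] <- factor(df[[v]], levels = aki_levels[[v]])
  }
  class(df) <- c("coded_cohort", "data.frame")
  df
}

#' Serialize a Bayesian network to canonical JSON
#' @param net A \code{bn}.
#' @param path Optional path; when given the JSON is written there.
#' @return The JSON string, invisibly when writing.
#' @export
bn_to_json <- function(net, path = NULL) {
  obj <- list(
    nodes = lapply(net$cpts, function(cpt) list(
      levels = cpt$levels, parents = cpt$parents,
      prob = unname(apply(cpt$prob, 1L, as.numeric, simplify = FALSE))
    )),
    arcs = apply(dag_arcs(net$dag), 1L, as.character, simplify = FALSE)
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Rebuild a Bayesian network from its JSON serialization
#' @param x JSON string or path.
#' @return A \code{bn}.
#' @export
bn_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  nodes <- names(obj$nodes)
  arcs <- if (length(obj$arcs)) do.call(rbind, lapply(obj$arcs, unlist)) else NULL
  dag <- bn_dag(nodes, arcs)
  lev <- lapply(obj$nodes, function(nd) unlist(nd$levels))
  cpts <- list()
  for (nd in nodes) {
    spec <- obj$nodes[[nd]]
    parents <- as.character(unlist(spec$parents))
    prob <- do.call(rbind, lapply(spec$prob, unlist))
    cpts[[nd]] <- bn_cpt(nd, lev[[nd]], parents, lev, prob)
  }
  bayes_net(dag, cpts)
}

#' Export a network in the Bayesian Interchange Format (BIF)
#'
#' Plain-text BIF for interoperability with standard BN tools.
#' @param net A \code{bn}.
#' @param path Output path.
#' @param name Network name.
#' @export
write_bif <- function(net, path, name = "network") {
  lines <- c(sprintf("network %s {", name), "}")
  for (nd in net$dag$nodes) {
    cpt <- net$cpts[[nd]]
    lines <- c(lines,
               sprintf("variable %s {", nd),
               sprintf("  type discrete [ %d ] { %s };", length(cpt$levels),
                       paste(cpt$levels, collapse = ", ")),
               "}")
  }
  fmt <- function(p) paste(format(p, digits = 17, trim = TRUE, scientific = FALSE), collapse = ", ")
  for (nd in net$dag$nodes) {
    cpt <- net$cpts[[nd]]
    if (!length(cpt$parents)) {
      lines <- c(lines, sprintf("probability ( %s ) {", nd),
                 sprintf("  table %s;", fmt(cpt$prob[1L, ])), "}")
    } else {
      grid <- do.call(expand.grid, c(cpt$parent_levels, stringsAsFactors = FALSE))
      body <- vapply(seq_len(nrow(grid)), function(i) {
        sprintf("  ( %s ) %s;", paste(unlist(grid[i, ]), collapse = ", "),
                fmt(cpt$prob[i, ]))
      }, "")
      lines <- c(lines,
                 sprintf("probability ( %s | %s ) {", nd, paste(cpt$parents, collapse = ", ")),
                 body, "}")
    }
  }
  writeLines(lines, path)
  invisible(path)
}
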