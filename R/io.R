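## Tabular readers/writers and model serialization. Cohorts travel as
## delimited text with samples as rows (human convention) and are transposed
## to the columns-as-samples convention internally. Models are written as
## directories of delimited matrices plus a JSON manifest; numbers use 17
## significant digits so doubles round-trip exactly.

fmt_num <- function(x) sprintf("%.17g", x)

write_matrix_txt <- function(m, path) {
  lines <- apply(m, 1L, function(r) paste(fmt_num(r), collapse = ","))
  writeLines(lines, path)
}

read_matrix_txt <- function(path) {
  lines <- readLines(path)
  do.call(rbind, lapply(strsplit(lines, ",", fixed = TRUE), as.numeric))
}

#' Write a cohort to delimited text
#'
#' One row per sample with header `subject_id, eye_id, label, v1..vd`.
#' Values are written with full precision so a read-back is bit-identical.
#'
#' @param cohort A [vf_cohort()].
#' @param path Output file.
#' @param delimiter Field separator (default comma).
#' @export
write_cohort <- function(cohort, path, delimiter = ",") {
  if (!inherits(cohort, "vf_cohort")) fail_input("cohort must be a vf_cohort")
  d <- nrow(cohort$features)
  header <- paste(c("subject_id", "eye_id", "label", paste0("v", seq_len(d))),
                  collapse = delimiter)
  body <- vapply(seq_len(ncol(cohort$features)), function(i) {
    paste(c(cohort$subject_ids[i], cohort$eye_ids[i], cohort$labels[i],
            fmt_num(cohort$features[, i])), collapse = delimiter)
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a cohort from delimited text
#'
#' Expects a header with `subject_id`, `eye_id`, `label` and measurement
#' columns `v1..vd`. If reliability columns `fp_rate`, `fn_rate`, `fl_rate`
#' are present, rows with any rate of 0.33 or more are dropped (the
#' perimetric reliability criterion of < 33% false positives/negatives and
#' fixation losses) with a logged count; absent columns mean no filtering.
#' Non-numeric cells, labels outside {0, 1} and inconsistent dimensions
#' raise a parse error naming the offending row.
#'
#' @param path Input file.
#' @param delimiter Field separator (default comma).
#' @return A [vf_cohort()].
#' @export
read_cohort <- function(path, delimiter = ",") {
  if (!file.exists(path)) fail_input("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = NA)
  required <- c("subject_id", "eye_id", "label")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    fail_input("missing header field(s): ", paste(missing, collapse = ", "))
  }
  vcols <- grep("^v[0-9]+$", names(df), value = TRUE)
  if (length(vcols) == 0L) fail_input("no measurement columns v1..vd found")
  vcols <- vcols[order(as.integer(sub("^v", "", vcols)))]

  rel_cols <- intersect(c("fp_rate", "fn_rate", "fl_rate"), names(df))
  if (length(rel_cols) > 0L) {
    ok <- rep(TRUE, nrow(df))
    for (rc in rel_cols) ok <- ok & (as.numeric(df[[rc]]) < 0.33)
    n_drop <- sum(!ok)
    if (n_drop > 0L) {
      vf_log("info", "dropped %d unreliable row(s) (reliability >= 0.33)", n_drop)
    }
    df <- df[ok, , drop = FALSE]
    if (nrow(df) == 0L) fail_input("no rows pass the reliability filter")
  }

  lab <- suppressWarnings(as.numeric(df$label))
  bad <- which(is.na(lab) | !(lab %in% c(0, 1)))
  if (length(bad) > 0L) {
    fail_input("invalid label in row ", bad[1L], ": ", df$label[bad[1L]])
  }
  V <- matrix(NA_real_, nrow(df), length(vcols))
  for (j in seq_along(vcols)) {
    col <- suppressWarnings(as.numeric(df[[vcols[j]]]))
    bad <- which(!is.finite(col))
    if (length(bad) > 0L) {
      fail_input("non-numeric or non-finite value in row ", bad[1L],
                 ", column ", vcols[j])
    }
    V[, j] <- col
  }
  cohort <- vf_cohort(t(V), as.integer(lab), df$subject_id, df$eye_id)
  vf_log("info", "read cohort: %d samples x %d measurements from %s",
         ncol(cohort$features), nrow(cohort$features), path)
  cohort
}

## ---- model serialization -------------------------------------------------

save_aa_layer <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_txt(model$B, file.path(dir, "B.csv"))
  write_matrix_txt(model$A, file.path(dir, "A.csv"))
  write_matrix_txt(model$D, file.path(dir, "D.csv"))
  manifest <- list(class = "aa_model", k = model$k, d = model$d, n = model$n,
                   objective_trace = model$objective_trace,
                   converged = model$converged,
                   n_iterations = model$n_iterations, rss = model$rss,
                   norm_X2 = model$norm_X2, init = model$init,
                   seed = model$seed, tol = model$tol)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

load_aa_layer <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  structure(list(B = read_matrix_txt(file.path(dir, "B.csv")),
                 A = read_matrix_txt(file.path(dir, "A.csv")),
                 D = read_matrix_txt(file.path(dir, "D.csv")),
                 k = man$k, d = man$d, n = man$n,
                 objective_trace = man$objective_trace,
                 converged = man$converged, n_iterations = man$n_iterations,
                 rss = man$rss, norm_X2 = man$norm_X2,
                 init = man$init, seed = man$seed, tol = man$tol),
            class = "aa_model")
}

#' Save a deep archetypal model to a directory
#'
#' Each layer's factor matrices are written as delimited text under
#' `layer1..layerL`, with a JSON manifest recording shapes, atom counts and
#' settings; the reload is bit-stable.
#'
#' @param model A `"daa_model"` (an `"aa_model"` is saved as a one-layer
#'   model).
#' @param dir Output directory (created if needed).
#' @export
save_daa_model <- function(model, dir) {
  if (inherits(model, "aa_model")) {
    model <- structure(list(layers = list(model), L = 1L, k_per_layer = model$k,
                            composite_dictionaries = list(model$D),
                            d = model$d, n = model$n, seed = model$seed),
                       class = "daa_model")
  }
  if (!inherits(model, "daa_model")) fail_input("model must be a daa_model")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (l in seq_len(model$L)) {
    save_aa_layer(model$layers[[l]], file.path(dir, sprintf("layer%d", l)))
  }
  manifest <- list(class = "daa_model", L = model$L,
                   k_per_layer = model$k_per_layer,
                   d = model$d, n = model$n, seed = model$seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a deep archetypal model saved with [save_daa_model()]
#'
#' @param dir Model directory.
#' @return A `"daa_model"` (composite dictionaries are recomposed from the
#'   per-layer factors).
#' @export
load_daa_model <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  L <- as.integer(man$L)
  layers <- lapply(seq_len(L), function(l) {
    load_aa_layer(file.path(dir, sprintf("layer%d", l)))
  })
  composite <- vector("list", L)
  composite[[1L]] <- layers[[1L]]$D
  if (L > 1L) {
    for (i in 2L:L) composite[[i]] <- composite[[i - 1L]] %*% layers[[i]]$D
  }
  structure(list(layers = layers, L = L,
                 k_per_layer = as.integer(man$k_per_layer),
                 composite_dictionaries = composite,
                 d = man$d, n = man$n, seed = man$seed),
            class = "daa_model")
}

#' Save a class-balanced bagging ensemble to a directory
#'
#' Per-member weight matrices as delimited text plus a JSON manifest with
#' the partition indices, base-network settings and seed.
#'
#' @param model A `"bagging_model"`.
#' @param dir Output directory.
#' @export
save_ensemble <- function(model, dir) {
  if (!inherits(model, "bagging_model")) fail_input("model must be a bagging_model")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(model$members)) {
    mdir <- file.path(dir, sprintf("member%d", i))
    dir.create(mdir, showWarnings = FALSE)
    net <- model$members[[i]]
    write_matrix_txt(net$W1, file.path(mdir, "W1.csv"))
    write_matrix_txt(matrix(net$b1, nrow = 1L), file.path(mdir, "b1.csv"))
    write_matrix_txt(net$W2, file.path(mdir, "W2.csv"))
    write_matrix_txt(matrix(c(net$b2, net$mu, net$sd), nrow = 1L),
                     file.path(mdir, "rest.csv"))
  }
  manifest <- list(class = "bagging_model",
                   partition = lapply(model$partition, as.integer),
                   base_spec = model$base_spec, seed = model$seed,
                   n_features = model$n_features,
                   n_members = length(model$members))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load an ensemble saved with [save_ensemble()]
#'
#' @param dir Ensemble directory.
#' @return A `"bagging_model"`.
#' @export
load_ensemble <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  p <- man$n_features
  members <- lapply(seq_len(man$n_members), function(i) {
    mdir <- file.path(dir, sprintf("member%d", i))
    W1 <- read_matrix_txt(file.path(mdir, "W1.csv"))
    b1 <- drop(read_matrix_txt(file.path(mdir, "b1.csv")))
    W2 <- read_matrix_txt(file.path(mdir, "W2.csv"))
    rest <- drop(read_matrix_txt(file.path(mdir, "rest.csv")))
    list(W1 = W1, b1 = b1, W2 = W2, b2 = rest[1L],
         mu = rest[2L:(p + 1L)], sd = rest[(p + 2L):(2L * p + 1L)],
         hidden = ncol(W1), p = p)
  })
  part <- man$partition
  if (is.matrix(part)) {       # equal-length subsets simplify to a matrix
    part <- lapply(seq_len(nrow(part)), function(i) part[i, ])
  }
  partition <- lapply(part, as.integer)
  structure(list(partition = partition, members = members,
                 base_spec = man$base_spec, seed = man$seed,
                 n_features = man$n_features),
            class = "bagging_model")
}

#' Write convex codes as a cohort-style feature table
#'
#' The codes are written with measurement columns `v1..vk` so the result can
#' be consumed by [read_cohort()] again (e.g. to train a classifier on
#' transformed features).
#'
#' @param codes k x m code matrix (columns = samples).
#' @param cohort The source [vf_cohort()] providing ids and labels.
#' @param path Output file.
#' @param delimiter Field separator.
#' @export
write_features <- function(codes, cohort, path, delimiter = ",") {
  out <- vf_cohort(codes, cohort$labels, cohort$subject_ids, cohort$eye_ids)
  write_cohort(out, path, delimiter)
}
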