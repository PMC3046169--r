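#' Fit a hot-spot prediction ensemble
#'
#' The main fitting function. From a labelled per-residue feature table it
#' (i) estimates feature/ddG correlations and keeps the baseline feature
#' set; (ii) grid-searches the general linear SVM's hyper-parameters by
#' cluster-aware inner cross-validation; (iii) for each specialist amino
#' acid (Arg and Glu by default) runs the constrained subset-ensemble
#' search -- every specialist is trained on ALL mutations, only the
#' subset choice looks at the target amino acid; (iv) trains the final
#' general and specialist models on the full table.
#'
#' @param table Labelled feature table from
#'   \code{\link{build_feature_table}} or
#'   \code{\link{generate_feature_dataset}}.
#' @param config \code{\link{training_config}}.
#' @param specialists Amino acids that get specialist classifiers.
#' @param r_min Baseline correlation floor.
#' @param r_max Redundancy threshold for candidate subsets.
#' @param k_inner Inner fold count for selection and grid search.
#' @return Object of class \code{hspred}: list with \code{model_X},
#'   \code{model_R}, \code{model_E} (or other specialists; \code{NULL}
#'   when not fitted), \code{baseline}, \code{selection} (per-specialist
#'   report), \code{stats}, \code{config}.
#' @seealso \code{\link{predict.hspred}}, \code{\link{predict_complex}},
#'   \code{\link{nested_cv}}
#' @export
hspred <- function(table, config = training_config(),
                   specialists = c("R", "E"), r_min = 0.2, r_max = 0.8,
                   k_inner = 3L) {
  if (!"label" %in% names(table)) stop("feature table is not labelled")
  # inner folds for full-data selection: a flat k_inner split of all clusters
  flat <- make_cluster_folds(table$cluster_id,
                             k_outer = min(k_inner,
                                           length(unique(table$cluster_id))),
                             k_inner = 2L, seed = config$seed)
  inner <- lapply(flat$outer, function(f)
    list(train_clusters = f$train_clusters,
         test_clusters = f$test_clusters))

  corr <- feature_ddg_correlation(table)
  base <- baseline_feature_set(corr, r_min)
  gs <- .grid_search(table, base, inner, config)
  st <- standardize(table, "fit")
  model_X <- train_linear_svm(st$table, base, gs$C, gs$class_weight,
                              stats = st$stats)
  fit <- list(model_X = model_X, model_R = NULL, model_E = NULL,
              baseline = base, correlations = corr,
              selection = list(), stats = st$stats,
              config = list(training = config, r_min = r_min,
                            r_max = r_max, k_inner = k_inner,
                            specialists = specialists))
  for (aa in specialists) {
    if (!any(table$wt_aa == aa & table$label == 1)) {
      stop("cannot build the ", aa,
           " specialist: no hot-spot rows of that amino acid")
    }
    fmat <- abs(stats::cor(as.matrix(table[, base, drop = FALSE])))
    excl <- redundancy_pairs(fmat, r_max)
    extra <- if (aa == "R" && !"coulomb_sc_intra" %in% base)
      "coulomb_sc_intra" else NULL
    cands <- enumerate_candidate_subsets(base, excl, c(3L, 4L), extra)
    sel <- select_best_subset(table, cands, aa, inner, config)
    m <- train_linear_svm(st$table, sel$feature_ids, sel$C,
                          sel$class_weight, stats = st$stats)
    fit[[paste0("model_", aa)]] <- m
    fit$selection[[aa]] <- sel
  }
  structure(fit, class = "hspred")
}

#' @export
print.hspred <- function(x, ...) {
  cat("Hot-spot prediction ensemble\n")
  cat("  general model: ", length(x$model_X$feature_ids), " features {",
      paste(x$model_X$feature_ids, collapse = ", "), "}\n", sep = "")
  for (aa in x$config$specialists) {
    m <- x[[paste0("model_", aa)]]
    if (is.null(m)) next
    cat("  ", aa, " specialist: {",
        paste(m$feature_ids, collapse = ", "), "}\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.hspred <- function(object, ...) {
  cat("Hot-spot prediction ensemble\n\n")
  cat("Feature/ddG correlations (|r|):\n")
  print(round(object$correlations, 3))
  cat("\nBaseline feature set (|r| >", object$config$r_min, "):\n  ",
      paste(object$baseline, collapse = ", "), "\n")
  cat("\nScoring-function weights:\n")
  print(round(coef(object), 4))
  for (aa in names(object$selection)) {
    s <- object$selection[[aa]]
    cat("\n", aa, " specialist selection: inner-CV F1 = ",
        round(s$f1, 3), ", C = ", s$C, ", class weight = ",
        s$class_weight, "\n", sep = "")
  }
  invisible(object)
}

#' Scoring-function weights of the ensemble
#'
#' Weight of every energy term in each model's linear scoring function
#' (absent terms are NA) plus the decision threshold, mirroring the usual
#' published weight-table layout.
#'
#' @param object \code{hspred} ensemble.
#' @param ... Unused.
#' @return Matrix: rows are the 12 features plus \code{threshold}, one
#'   column per model.
#' @export
coef.hspred <- function(object, ...) {
  models <- list(X = object$model_X)
  for (aa in object$config$specialists) {
    m <- object[[paste0("model_", aa)]]
    if (!is.null(m)) models[[aa]] <- m
  }
  out <- matrix(NA_real_, nrow = 13, ncol = length(models),
                dimnames = list(c(feature_names(), "threshold"),
                                paste0("SVM_", names(models))))
  for (k in seq_along(models)) {
    m <- models[[k]]
    out[m$feature_ids, k] <- m$weights
    out["threshold", k] <- m$threshold
  }
  out
}

#' Predict hot spots from a feature table
#'
#' Routes each row by wild-type amino acid to the general or specialist
#' model, scores it and calls hot spots at score > 0.
#'
#' @param object \code{hspred} ensemble.
#' @param newdata Feature table (raw scale) with \code{wt_aa} and the 12
#'   feature columns.
#' @param ... Unused.
#' @return data.frame \code{(wt_aa, score, hotspot_call, model)} aligned
#'   with \code{newdata} rows (plus identity columns when present).
#' @export
predict.hspred <- function(object, newdata, ...) {
  n <- nrow(newdata)
  s <- numeric(n)
  used <- character(n)
  for (i in seq_len(n)) {
    m <- route(object, newdata$wt_aa[i])
    used[i] <- if (identical(m, object$model_X)) "X" else newdata$wt_aa[i]
    s[i] <- score(m, newdata[i, , drop = FALSE])
  }
  id_cols <- intersect(c("complex_id", "chain", "resnum"), names(newdata))
  out <- cbind(newdata[, id_cols, drop = FALSE],
               data.frame(wt_aa = newdata$wt_aa, score = s,
                          hotspot_call = classify(s), model = used,
                          stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Predict hot spots for every interface residue of a complex
#'
#' Runs the full per-structure pipeline: candidate interface residues,
#' 12-component energy vectors, routing, scoring and calling. Output
#' mirrors the per-residue prediction table of the original web service.
#'
#' @param ensemble \code{hspred} ensemble.
#' @param complex \code{hspred_complex}.
#' @param shell_radius Shell radius, Angstrom.
#' @param contact_cutoff Interface contact distance, Angstrom.
#' @param config Energy constants.
#' @return data.frame \code{(chain, resnum, wt_aa, score, hotspot_call)}
#'   sorted by chain then residue number.
#' @export
predict_complex <- function(ensemble, complex,
                            shell_radius = energy_config()$shell_radius,
                            contact_cutoff = energy_config()$contact_cutoff,
                            config = energy_config()) {
  stopifnot(inherits(ensemble, "hspred"), inherits(complex, "hspred_complex"))
  sites <- find_interface_residues(complex, contact_cutoff)
  out <- data.frame(chain = character(0), resnum = character(0),
                    wt_aa = character(0), score = numeric(0),
                    hotspot_call = integer(0), stringsAsFactors = FALSE)
  if (nrow(sites) == 0) return(out)
  for (i in seq_len(nrow(sites))) {
    site <- sites[i, ]
    ev <- energy_vector(complex, site, shell_radius, config)
    m <- route(ensemble, site$wt)
    s <- score(m, ev)
    out <- rbind(out, data.frame(chain = site$chain, resnum = site$resno,
                                 wt_aa = site$wt, score = s,
                                 hotspot_call = classify(s),
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Serialize / restore an ensemble as human-readable weight tables
#'
#' Writes one tab-separated weight table per model (feature, weight, plus
#' a threshold row), the standardization statistics and the fitting
#' configuration. \code{read_hspred} restores an ensemble that scores
#' identically without any training backend.
#'
#' @param ensemble \code{hspred} ensemble.
#' @param dir Directory for the bundle (created if needed).
#' @return \code{dir} (write) or the restored \code{hspred} (read).
#' @export
write_hspred <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "hspred"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  models <- c(list(X = ensemble$model_X),
              stats::setNames(
                lapply(ensemble$config$specialists,
                       function(aa) ensemble[[paste0("model_", aa)]]),
                ensemble$config$specialists))
  for (nm in names(models)) {
    m <- models[[nm]]
    if (is.null(m)) next
    tab <- data.frame(
      feature = c(m$feature_ids, "__threshold__", "__C__",
                  "__class_weight__"),
      weight = c(unname(m$weights), m$threshold, m$meta$C,
                 m$meta$class_weight))
    utils::write.table(tab, file.path(dir, paste0("model_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (length(ensemble$selection)) {
    rep <- do.call(rbind, lapply(names(ensemble$selection), function(aa) {
      s <- ensemble$selection[[aa]]
      data.frame(subset = paste(s$feature_ids, collapse = ","),
                 target_aa = aa, inner_f1 = s$f1, C = s$C,
                 class_weight = s$class_weight)
    }))
    utils::write.table(rep, file.path(dir, "selection.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  st <- ensemble$stats
  utils::write.table(
    data.frame(feature = names(st$mean), mean = unname(st$mean),
               sd = unname(st$sd)),
    file.path(dir, "standardization.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  yaml::write_yaml(
    list(specialists = as.list(ensemble$config$specialists),
         r_min = ensemble$config$r_min, r_max = ensemble$config$r_max,
         baseline = as.list(ensemble$baseline)),
    file.path(dir, "ensemble.yml"))
  invisible(dir)
}

#' @rdname write_hspred
#' @export
read_hspred <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "ensemble.yml"))
  stt <- utils::read.table(file.path(dir, "standardization.tsv"),
                           header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stats <- list(mean = stats::setNames(stt$mean, stt$feature),
                sd = stats::setNames(stt$sd, stt$feature))
  read_model <- function(nm) {
    path <- file.path(dir, paste0("model_", nm, ".tsv"))
    if (!file.exists(path)) return(NULL)
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    special <- startsWith(tab$feature, "__")
    w <- stats::setNames(tab$weight[!special], tab$feature[!special])
    get <- function(key) tab$weight[tab$feature == key]
    structure(list(feature_ids = names(w), weights = w,
                   threshold = get("__threshold__"),
                   meta = list(C = get("__C__"),
                               class_weight = get("__class_weight__"),
                               stats = stats)),
              class = "hspred_svm")
  }
  specialists <- unlist(meta$specialists)
  fit <- list(model_X = read_model("X"), model_R = NULL, model_E = NULL,
              baseline = unlist(meta$baseline), correlations = NULL,
              selection = list(), stats = stats,
              config = list(training = NULL, r_min = meta$r_min,
                            r_max = meta$r_max,
                            specialists = specialists))
  for (aa in specialists) fit[[paste0("model_", aa)]] <- read_model(aa)
  structure(fit, class = "hspred")
}
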