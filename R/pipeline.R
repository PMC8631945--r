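# End-to-end orchestration: landmarks -> composite fossil -> lever
# geometry -> MA curves -> polynomial/AIC functional space -> PCA ->
# phylogenetic signal -> pPCA, with tabular outputs and a structured
# report. The exported functions are the package's interface; file
# outputs are optional and byte-stable for a fixed config and seed.

#' Validate pipeline inputs
#'
#' Cross-checks landmark configurations, fossil fragments, tree tips
#' and metadata before any computation. Never modifies data; returns a
#' report listing every check with status `pass`, `warn` or `fail`.
#'
#' @param configs Named list of [landmark_config]s (extant specimens).
#' @param tree Optional [ape::phylo] tree.
#' @param diet Optional named vector of diet classes.
#' @param fossil_copies Optional list of fossil fragment configurations.
#' @param fossil_id Tip label expected for the composite fossil.
#' @return An object of class `validation_report` (data frame of
#'   checks plus an `ok` flag).
#' @export
validate_inputs <- function(configs, tree = NULL, diet = NULL,
                            fossil_copies = NULL, fossil_id = "CFMR") {
  checks <- list()
  add <- function(name, status, message = "")
    checks[[length(checks) + 1L]] <<- data.frame(
      check = name, status = status, message = message,
      stringsAsFactors = FALSE)

  ids <- vapply(configs, `[[`, character(1), "specimen_id")
  if (anyDuplicated(ids))
    add("specimen_ids", "fail", paste("duplicate ids:",
        paste(ids[duplicated(ids)], collapse = ", ")))
  else add("specimen_ids", "pass", sprintf("%d unique specimens",
                                           length(ids)))

  role_ok <- vapply(configs, function(cfg) {
    r <- cfg$roles
    !is.null(r) && sum(r == "adductor_attachment") == 1 &&
      sum(r == "edge_point") >= 4 &&
      any(r %in% c("condyle_anterior", "condyle_posterior"))
  }, logical(1))
  if (all(role_ok)) add("lever_roles", "pass",
                        "joint, adductor and >=4 edge points everywhere")
  else add("lever_roles", "fail",
           paste("incomplete lever roles:",
                 paste(ids[!role_ok], collapse = ", ")))

  if (!is.null(fossil_copies)) {
    if (length(fossil_copies) >= 2) {
      labsets <- lapply(fossil_copies,
                        function(cfg) sort(rownames(cfg$points)))
      if (all(vapply(labsets[-1], identical, logical(1), labsets[[1]])))
        add("fossil_fragments", "pass",
            sprintf("%d fragments, shared label set",
                    length(fossil_copies)))
      else add("fossil_fragments", "fail",
               "fossil fragments do not share a label set")
    } else add("fossil_fragments", "fail",
               "need >= 2 fossil fragments for a composite")
  }

  if (!is.null(tree)) {
    tips <- tree$tip.label
    expected <- c(ids, if (!is.null(fossil_copies)) fossil_id)
    extra <- setdiff(tips, expected)
    missing_tips <- setdiff(expected, tips)
    if (length(missing_tips))
      add("tree_tips", "fail", paste("specimens missing from tree:",
          paste(missing_tips, collapse = ", ")))
    else if (length(extra))
      add("tree_tips", "warn", paste("extra tip(s) in tree:",
          paste(extra, collapse = ", ")))
    else add("tree_tips", "pass", "tips match specimens")
    if (is.null(tree$edge.length))
      add("branch_lengths", "fail", "tree has no branch lengths")
    else if (any(tree$edge.length < 0))
      add("branch_lengths", "fail", "negative branch lengths")
    else add("branch_lengths", "pass", "")
  }

  if (!is.null(diet)) {
    uncovered <- setdiff(ids, names(diet))
    if (length(uncovered))
      add("diet_metadata", "fail", paste("no diet class for:",
          paste(uncovered, collapse = ", ")))
    else add("diet_metadata", "pass", "")
  }

  df <- do.call(rbind, checks)
  structure(list(checks = df, ok = !any(df$status == "fail")),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation:", if (x$ok) "OK" else "FAILED", "\n")
  for (i in seq_len(nrow(x$checks)))
    cat(sprintf("  [%s] %s%s\n", x$checks$status[i], x$checks$check[i],
                ifelse(x$checks$message[i] == "", "",
                       paste0(": ", x$checks$message[i]))))
  invisible(x)
}

#' Run the full comparative pipeline
#'
#' Orchestrates every stage: builds the composite fossil from its
#' fragments (reflecting to a common side first), derives lever
#' geometry and MA curves for all terminal units, selects the common
#' polynomial order by AIC, assembles the coefficient matrix, runs PCA
#' and — unless `skip_phylo` — Blomberg's K per descriptor, the
#' multivariate K with a permutation test, and phylogenetic PCA over
#' the tree including the fossil tip.
#'
#' @param study An `ma_study` bundle from [make_study]; alternatively
#'   pass `configs`, `tree`, `diet`, `fossil_copies` explicitly.
#' @param configs,tree,diet,fossil_copies Individual inputs, used when
#'   `study` is `NULL`.
#' @param fossil_id Tip label of the composite fossil.
#' @param n_points MA curve sampling density (default 100).
#' @param candidate_orders Polynomial orders compared by AIC.
#' @param descriptor_policy Passed to [build_coefficient_matrix].
#' @param scale_to_correlation Passed to [functional_pca].
#' @param n_permutations Permutations for the signal test (default
#'   9999). Set to 0 to skip the permutation test.
#' @param seed Integer seed; required whenever `n_permutations > 0`.
#' @param skip_phylo Skip the tree-based stages (no tree needed).
#' @param output_dir Optional directory; when given, every stage table
#'   is written as CSV, a JSON report and a PC1-PC2 scatter (PDF) are
#'   emitted.
#' @return An object of class `ma_pipeline_report` collecting all
#'   stage results.
#' @export
run_pipeline <- function(study = NULL, configs = NULL, tree = NULL,
                         diet = NULL, fossil_copies = NULL,
                         fossil_id = "CFMR",
                         n_points = 100L, candidate_orders = 1:8,
                         descriptor_policy = "exclude_intercept",
                         scale_to_correlation = FALSE,
                         n_permutations = 9999L, seed = NULL,
                         skip_phylo = FALSE, output_dir = NULL) {
  if (!is.null(study)) {
    stopifnot(inherits(study, "ma_study"))
    configs <- study$configs
    tree <- study$tree
    diet <- study$diet
    fossil_copies <- study$fossil_copies
    fossil_id <- study$fossil_id
  }
  if (!skip_phylo && n_permutations > 0 && is.null(seed))
    stop("a seed is required when permutations are requested; ",
         "nothing was computed")
  val <- validate_inputs(configs, tree = if (!skip_phylo) tree,
                         diet = diet, fossil_copies = fossil_copies,
                         fossil_id = fossil_id)
  if (!val$ok) {
    bad <- val$checks[val$checks$status == "fail", ]
    stop("input validation failed:\n  ",
         paste(bad$check, bad$message, sep = ": ", collapse = "\n  "))
  }

  units <- configs
  fossil_cfg <- NULL
  if (!is.null(fossil_copies)) {
    sides <- vapply(fossil_copies, `[[`, character(1), "side")
    ref_side <- if (all(is.na(sides))) NA else names(
      sort(table(sides), decreasing = TRUE))[1]
    copies <- if (is.na(ref_side)) fossil_copies else
      lapply(fossil_copies, reflect_to_reference, reference_side = ref_side)
    fossil_cfg <- composite_representation(copies, specimen_id = fossil_id)
    units <- c(units, stats::setNames(list(fossil_cfg), fossil_id))
  }

  curves <- lapply(units, function(cfg)
    ma_curve(lever_geometry_from_landmarks(cfg), n_points = n_points))
  sel <- select_order_by_aic(curves, candidate_orders)
  fits <- lapply(curves, fit_polynomial, order = sel$best_order)
  space <- build_coefficient_matrix(fits, policy = descriptor_policy)
  space <- functional_pca(space, scale_to_correlation = scale_to_correlation)

  signal <- NULL
  signal_by_descriptor <- NULL
  ppca <- NULL
  if (!skip_phylo) {
    X <- space$coefficient_matrix
    prep_tree <- tree
    signal_by_descriptor <- vapply(colnames(X), function(j)
      blomberg_k(X[, j], prep_tree), numeric(1))
    if (n_permutations > 0)
      signal <- permutation_test(X, prep_tree,
                                 n_permutations = n_permutations,
                                 seed = seed)
    ppca <- phylogenetic_pca(X, prep_tree)
  }

  fossil_position <- NULL
  if (!is.null(fossil_cfg) && !is.null(diet)) {
    sc <- space$pc_scores
    extant <- setdiff(rownames(sc), fossil_id)
    cent <- tapply(sc[extant, 1], diet[extant], mean)
    fossil_position <- list(
      fossil_pc1 = unname(sc[fossil_id, 1]),
      class_centroids_pc1 = cent,
      between_herb_carn = {
        rng <- range(cent[c("herbivore", "carnivore")])
        sc[fossil_id, 1] >= rng[1] && sc[fossil_id, 1] <= rng[2]
      })
  }

  report <- structure(list(
    n_units = length(units), fossil_id = if (!is.null(fossil_cfg))
      fossil_id, selected_order = sel$best_order,
    aic_by_order = sel$aic_by_order, curves = curves, fits = fits,
    space = space, signal_by_descriptor = signal_by_descriptor,
    signal = signal, ppca = ppca, diet = diet,
    fossil_position = fossil_position,
    config = list(n_points = n_points,
                  candidate_orders = candidate_orders,
                  descriptor_policy = descriptor_policy,
                  scale_to_correlation = scale_to_correlation,
                  n_permutations = n_permutations, seed = seed,
                  skip_phylo = skip_phylo)),
    class = "ma_pipeline_report")
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

#' @export
print.ma_pipeline_report <- function(x, ...) {
  cat("MA pipeline report —", x$n_units, "terminal units\n")
  cat("  selected polynomial order:", x$selected_order,
      sprintf("(AIC %.1f)", x$aic_by_order[as.character(x$selected_order)]),
      "\n")
  ve <- x$space$variance_explained
  cat(sprintf("  PCA: first %d PCs explain %.1f%%\n",
              min(4, length(ve)), sum(ve[seq_len(min(4, length(ve)))])))
  if (!is.null(x$signal))
    cat(sprintf("  %s = %.5f, p = %.4g (%d permutations)\n",
                x$signal$statistic_name, x$signal$observed,
                x$signal$p_value, x$signal$n_permutations))
  if (!is.null(x$ppca)) {
    vp <- x$ppca$variance_explained
    cat(sprintf("  pPCA: first %d PCs explain %.1f%%\n",
                min(4, length(vp)), sum(vp[seq_len(min(4, length(vp)))])))
  }
  if (!is.null(x$fossil_position))
    cat(sprintf("  fossil PC1 = %.4f (herb/omn/carn centroids: %s)\n",
                x$fossil_position$fossil_pc1,
                paste(signif(x$fossil_position$class_centroids_pc1, 3),
                      collapse = "/")))
  invisible(x)
}

# write every stage table + JSON summary + PC scatter into output_dir
write_report <- function(report, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(output_dir, f)
  write_curve_table(report$curves, p("ma_curves.csv"))
  utils::write.csv(data.frame(order = names(report$aic_by_order),
                              aic = unname(report$aic_by_order)),
                   p("aic_table.csv"), row.names = FALSE)
  utils::write.csv(report$space$coefficient_matrix,
                   p("coefficients.csv"))
  utils::write.csv(report$space$pc_scores, p("pca_scores.csv"))
  utils::write.csv(report$space$pc_loadings, p("pca_loadings.csv"))
  if (!is.null(report$ppca)) {
    utils::write.csv(report$ppca$pc_scores, p("ppca_scores.csv"))
    utils::write.csv(report$ppca$pc_loadings, p("ppca_loadings.csv"))
  }
  summary <- list(
    n_units = report$n_units,
    selected_order = report$selected_order,
    aic_by_order = as.list(report$aic_by_order),
    pca_variance_explained = report$space$variance_explained,
    config = report$config)
  if (!is.null(report$signal))
    summary$signal <- list(statistic = report$signal$statistic_name,
                           observed = report$signal$observed,
                           p_value = report$signal$p_value,
                           n_permutations = report$signal$n_permutations,
                           seed = report$signal$seed)
  if (!is.null(report$signal_by_descriptor))
    summary$K_by_descriptor <- as.list(report$signal_by_descriptor)
  if (!is.null(report$ppca))
    summary$ppca_variance_explained <- report$ppca$variance_explained
  if (!is.null(report$fossil_position))
    summary$fossil_position <- report$fossil_position[
      c("fossil_pc1", "between_herb_carn")]
  jsonlite::write_json(summary, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  grDevices::pdf(p("functional_space.pdf"), width = 6, height = 5)
  plot_functional_space(report$space, groups = report$diet,
                        highlight = report$fossil_id,
                        main = "MA functional space")
  grDevices::dev.off()
  invisible(output_dir)
}
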