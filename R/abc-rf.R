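#' Summary-statistic vector for ABC
#'
#' Fixed-order vector of 37 statistics computed on the five geographic
#' groups (IND, NPT, ITP, BKP, SEP): per group the mean expected
#' heterozygosity, mean minor allele frequency and proportion of SNPs
#' polymorphic within the group (15 values); for each of the 10 group
#' pairs the Hudson FST and the Nei standard distance (20 values); and the
#' two admixture statistics f3(ITP; BKP, SEP) and f3(ITP; NPT, SEP).
#' Undefined entries (e.g. a distance between monomorphic groups) are
#' imputed as 0; the number of imputations is recorded in the
#' `"n_imputed"` attribute.
#'
#' @param ds a `genotype_dataset` whose `pop_map$breed` contains the five
#'   population codes IND, NPT, ITP, BKP, SEP (as produced by
#'   [simulate_dataset()]), or whose groups map onto them via
#'   `use_groups = TRUE`.
#' @param use_groups compute on `pop_map$group` labels translated from the
#'   five codes (default FALSE: breed codes are used directly).
#' @return Named numeric vector of length 37.
#' @export
summarize_dataset <- function(ds, use_groups = FALSE) {
  codes <- c("IND", "NPT", "ITP", "BKP", "SEP")
  lab <- if (use_groups) unname(group_of_pop[codes]) else codes
  by_group <- use_groups

  out <- numeric(0)
  for (k in seq_along(codes)) {
    g <- genotypes_of(ds, breed = if (by_group) NULL else lab[k],
                      group = if (by_group) lab[k] else NULL)
    p <- colMeans(g, na.rm = TRUE) / 2
    he <- 2 * p * (1 - p)
    maf <- pmin(p, 1 - p)
    v <- c(mean(he, na.rm = TRUE), mean(maf, na.rm = TRUE),
           mean(p > 0 & p < 1, na.rm = TRUE))
    names(v) <- paste0(codes[k], c("_He", "_MAF", "_polym"))
    out <- c(out, v)
  }
  for (i in 1:4) for (j in (i + 1):5) {
    v <- c(hudson_fst(ds, lab[i], lab[j], by_group = by_group),
           nei_distance(ds, lab[i], lab[j], by_group = by_group))
    names(v) <- paste0(codes[i], "_", codes[j], c("_fst", "_nei"))
    out <- c(out, v)
  }
  f3a <- f3_statistic(ds, lab[3], lab[4], lab[5], by_group = by_group)
  f3b <- f3_statistic(ds, lab[3], lab[2], lab[5], by_group = by_group)
  out <- c(out, f3_ITP_BKP_SEP = f3a, f3_ITP_NPT_SEP = f3b)

  bad <- !is.finite(out)
  out[bad] <- 0
  attr(out, "n_imputed") <- sum(bad)
  out
}

#' Build an ABC reference table
#'
#' For every scenario, draws `n_per_scenario` parameter vectors from the
#' priors, simulates a dataset for each and computes its summary vector.
#' Failed simulations (retry cap exhausted at the MAF floor) are skipped
#' with a message, so the design can become mildly unbalanced; the failure
#' count per scenario is recorded.
#'
#' @param scenarios list of `scenario_spec` (default all six built-ins).
#' @param priors a `prior_spec`.
#' @param n_per_scenario simulations per scenario.
#' @param simcfg a [sim_config()].
#' @param verbose print progress (default FALSE).
#' @return A `reference_table`: list with `scenario` (integer vector),
#'   `params` (matrix), `stats` (matrix) and `meta`.
#' @export
build_reference_table <- function(scenarios = build_builtin_scenarios(),
                                  priors = default_priors(),
                                  n_per_scenario = 500,
                                  simcfg = sim_config(),
                                  verbose = FALSE) {
  rows_sc <- integer(0)
  rows_par <- list()
  rows_st <- list()
  failures <- integer(length(scenarios))
  for (si in seq_along(scenarios)) {
    sc <- scenarios[[si]]
    for (rep in seq_len(n_per_scenario)) {
      par <- draw_params(priors, sc)
      ds <- tryCatch(simulate_dataset(sc, par, simcfg), error = function(e) e)
      if (inherits(ds, "error")) {
        failures[si] <- failures[si] + 1L
        message("simulation failure (scenario ", sc$id, "): ",
                conditionMessage(ds))
        next
      }
      rows_sc <- c(rows_sc, sc$id)
      rows_par[[length(rows_par) + 1L]] <- unclass(par)
      rows_st[[length(rows_st) + 1L]] <- as.numeric(summarize_dataset(ds))
    }
    if (verbose) message("scenario ", sc$id, ": ",
                         n_per_scenario - failures[si], " rows")
  }
  st <- do.call(rbind, rows_st)
  colnames(st) <- names(summary_stat_names())
  tab <- list(scenario = rows_sc,
              params = do.call(rbind, rows_par),
              stats = st,
              meta = list(n_per_scenario = n_per_scenario,
                          failures = failures, simcfg = simcfg,
                          priors = unclass(priors)))
  class(tab) <- "reference_table"
  tab
}

# canonical names/order of the 37 summary statistics (internal)
summary_stat_names <- function() {
  codes <- c("IND", "NPT", "ITP", "BKP", "SEP")
  nm <- character(0)
  for (k in codes) nm <- c(nm, paste0(k, c("_He", "_MAF", "_polym")))
  for (i in 1:4) for (j in (i + 1):5)
    nm <- c(nm, paste0(codes[i], "_", codes[j], c("_fst", "_nei")))
  nm <- c(nm, "f3_ITP_BKP_SEP", "f3_ITP_NPT_SEP")
  stats::setNames(seq_along(nm), nm)
}

#' @export
print.reference_table <- function(x, ...) {
  cat(sprintf("reference_table: %d rows (%s), %d summary statistics\n",
              length(x$scenario),
              paste(sprintf("scenario %d: %d", sort(unique(x$scenario)),
                            table(x$scenario)), collapse = ", "),
              ncol(x$stats)))
  invisible(x)
}

#' Append linear-discriminant axes to a reference table
#'
#' Fits a linear discriminant analysis of the summary statistics on the
#' scenario label (k - 1 axes for k scenarios) and appends the discriminant
#' coordinates to every table row and to the observed vector. The extra
#' axes sharpen random-forest scenario choice and support the prior
#' compatibility check.
#'
#' @param table a `reference_table`.
#' @param observed_summary the observed summary vector (length and order of
#'   [summarize_dataset()]).
#' @return List `table` (augmented), `observed` (augmented vector) and
#'   `lda` (the fitted `MASS::lda` object).
#' @export
add_lda_axes <- function(table, observed_summary) {
  X <- table$stats
  keep <- apply(X, 2, function(v) stats::sd(v) > 0)
  fit <- MASS::lda(X[, keep, drop = FALSE], grouping = factor(table$scenario))
  proj <- as.matrix(X[, keep, drop = FALSE]) %*% fit$scaling
  colnames(proj) <- paste0("LD", seq_len(ncol(proj)))
  obs <- as.numeric(observed_summary)[keep] %*% fit$scaling
  aug <- table
  aug$stats <- cbind(X, proj)
  obs_aug <- c(as.numeric(observed_summary), as.numeric(obs))
  names(obs_aug) <- colnames(aug$stats)
  list(table = aug, observed = obs_aug, lda = fit)
}

#' Prior compatibility of the observed data
#'
#' Projects the observed summary vector onto the reference table's linear
#' discriminant axes and flags it as compatible with the priors if every
#' coordinate lies within the [0.1%, 99.9%] empirical range of the
#' simulated cloud.
#'
#' @param table a `reference_table`.
#' @param observed observed summary vector.
#' @return List `compatible` (logical), `axes` (data frame with the
#'   observed coordinate, band and percentile per axis).
#' @export
prior_compatibility_check <- function(table, observed) {
  aug <- add_lda_axes(table, observed)
  ld_cols <- grep("^LD", colnames(aug$table$stats))
  cloud <- aug$table$stats[, ld_cols, drop = FALSE]
  obs <- aug$observed[ld_cols]
  rows <- lapply(seq_along(ld_cols), function(k) {
    band <- stats::quantile(cloud[, k], c(0.001, 0.999), names = FALSE)
    data.frame(axis = colnames(cloud)[k], observed = obs[k],
               lower = band[1], upper = band[2],
               percentile = mean(cloud[, k] <= obs[k]),
               inside = obs[k] >= band[1] & obs[k] <= band[2])
  })
  axes <- do.call(rbind, rows)
  list(compatible = all(axes$inside), axes = axes)
}

#' Fit the ABC random-forest scenario classifier
#'
#' The core model fit. Trains a random-forest classifier of the scenario
#' label on the reference table's summary statistics augmented with linear
#' discriminant axes, then trains a second, regression forest on the
#' indicator "the ensemble's out-of-bag prediction for this row is
#' correct", which converts classifier votes into a posterior probability
#' (vote share is not a posterior probability). With a `grouping`, scenario
#' labels are collapsed to set labels before training, giving set-level
#' model choice.
#'
#' @param table a `reference_table`.
#' @param observed_summary an observed summary vector used to anchor the
#'   LDA augmentation (any vector on the summary scale; axes are fitted on
#'   the table only).
#' @param grouping optional named list of integer vectors partitioning the
#'   scenario ids, e.g. `list(set1 = 1:3, set2 = 4:6)`.
#' @param n_trees number of trees (default 1000; fewer than 50 is refused
#'   as unstable).
#' @param seed integer seed for the forests.
#' @return An object of class `abc_rf` with `predict`, `print` and
#'   `summary` methods.
#' @seealso [rf_model_choice()] for the one-call interface,
#'   [rf_parameter_estimate()] for parameter posteriors.
#' @export
abc_rf <- function(table, observed_summary, grouping = NULL, n_trees = 1000,
                   seed = 1) {
  if (n_trees < 50) stop("n_trees < 50 refused: vote fractions too unstable")
  lab <- table$scenario
  if (!is.null(grouping)) {
    ids <- sort(unlist(grouping))
    if (any(duplicated(ids)) || !setequal(ids, unique(table$scenario)))
      stop("grouping must partition the scenario ids present in the table")
    lab <- rep(NA_character_, length(lab))
    for (nm in names(grouping)) lab[table$scenario %in% grouping[[nm]]] <- nm
  }
  y <- factor(lab)

  aug <- add_lda_axes(table, observed_summary)
  X <- as.data.frame(aug$table$stats)

  cls <- ranger::ranger(x = X, y = y, num.trees = n_trees,
                        keep.inbag = TRUE, num.threads = 1, seed = seed)

  # out-of-bag per-row ensemble prediction -> correctness indicator
  pt <- stats::predict(cls, X, predict.all = TRUE,
                       num.threads = 1)$predictions
  inbag <- matrix(unlist(cls$inbag.counts), ncol = n_trees)
  nlev <- nlevels(y)
  oob_pred <- integer(nrow(X))
  for (i in seq_len(nrow(X))) {
    v <- pt[i, inbag[i, ] == 0L]
    oob_pred[i] <- if (length(v)) which.max(tabulate(v, nlev)) else NA_integer_
  }
  correct <- as.numeric(oob_pred == as.integer(y))
  correct[is.na(correct)] <- 0
  reg <- ranger::ranger(x = X, y = correct, num.trees = n_trees,
                        num.threads = 1, seed = seed)

  fit <- list(classifier = cls, posterior_forest = reg, lda = aug$lda,
              levels = levels(y), grouping = grouping, n_trees = n_trees,
              stat_names = colnames(table$stats),
              oob_misclassification = mean(oob_pred != as.integer(y),
                                           na.rm = TRUE))
  class(fit) <- "abc_rf"
  fit
}

# project an observed summary vector onto the fit's feature space
augment_observed <- function(fit, observed) {
  obs <- as.numeric(observed)[seq_along(fit$stat_names)]
  keep <- rownames(fit$lda$scaling)
  idx <- match(keep, fit$stat_names)
  proj <- matrix(obs[idx], 1) %*% fit$lda$scaling
  x <- c(obs, as.numeric(proj))
  names(x) <- c(fit$stat_names, paste0("LD", seq_len(ncol(fit$lda$scaling))))
  as.data.frame(as.list(x))
}

#' Scenario choice for an observed dataset
#'
#' @param object a fitted `abc_rf`.
#' @param observed observed summary vector (length of
#'   [summarize_dataset()]).
#' @param ... unused.
#' @return A `model_choice` list: `votes` (per scenario or set, summing to
#'   the tree count), `selected`, `posterior_prob`.
#' @export
predict.abc_rf <- function(object, observed, ...) {
  newx <- augment_observed(object, observed)
  pt <- stats::predict(object$classifier, newx, predict.all = TRUE,
                       num.threads = 1)$predictions
  votes <- tabulate(as.integer(pt), length(object$levels))
  names(votes) <- object$levels
  sel <- object$levels[which.max(votes)]
  pp <- stats::predict(object$posterior_forest, newx,
                       num.threads = 1)$predictions
  out <- list(votes = votes, selected = sel,
              posterior_prob = min(max(pp, 0), 1),
              n_trees = object$n_trees)
  class(out) <- "model_choice"
  out
}

#' @export
print.model_choice <- function(x, ...) {
  cat("votes: ", paste(sprintf("%s=%d", names(x$votes), x$votes),
                       collapse = ", "), "\n", sep = "")
  cat(sprintf("selected: %s (%d/%d trees, posterior probability %.2f)\n",
              x$selected, max(x$votes), x$n_trees, x$posterior_prob))
  invisible(x)
}

#' @export
print.abc_rf <- function(x, ...) {
  cat(sprintf("abc_rf: %d trees over %d classes (%s)\n", x$n_trees,
              length(x$levels), paste(x$levels, collapse = ", ")))
  cat(sprintf("  out-of-bag misclassification: %.3f\n",
              x$oob_misclassification))
  invisible(x)
}

#' @export
summary.abc_rf <- function(object, ...) {
  print(object)
  invisible(object)
}

#' One-call scenario choice
#'
#' Convenience wrapper: fits [abc_rf()] on the table and predicts the
#' observed point.
#'
#' @inheritParams abc_rf
#' @param observed observed summary vector.
#' @return A `model_choice` (see [predict.abc_rf()]).
#' @export
rf_model_choice <- function(table, observed, n_trees = 1000, seed = 1) {
  predict(abc_rf(table, observed, n_trees = n_trees, seed = seed), observed)
}

#' @rdname rf_model_choice
#' @param grouping named list of integer vectors partitioning scenario ids.
#' @export
grouped_model_choice <- function(table, grouping, observed, n_trees = 1000,
                                 seed = 1) {
  predict(abc_rf(table, observed, grouping = grouping, n_trees = n_trees,
                 seed = seed), observed)
}

#' Quantile-forest posterior for one parameter
#'
#' Trains a quantile regression forest of the parameter on the augmented
#' summary statistics, usually on the table restricted to the selected
#' scenario, and reads the posterior median and 0.05/0.95 quantiles at the
#' observed point from the forest's leaf co-occurrence weights.
#'
#' @param table a `reference_table` (restrict to the chosen scenario with
#'   `scenario_id`).
#' @param observed observed summary vector.
#' @param param parameter name (column of `table$params`).
#' @param scenario_id optional scenario id to restrict the table to.
#' @param n_trees number of trees (default 1000).
#' @param seed forest seed.
#' @param gen_time generation time in years used for the derived
#'   years-before-present columns (default 2.5).
#' @return A `param_posterior`: parameter name, `median`, `q05`, `q95` (in
#'   generations) and their floor-converted YBP counterparts.
#' @export
rf_parameter_estimate <- function(table, observed, param, scenario_id = NULL,
                                  n_trees = 1000, seed = 1, gen_time = 2.5) {
  if (!param %in% colnames(table$params))
    stop("unknown parameter: ", param)
  keep <- if (is.null(scenario_id)) seq_along(table$scenario) else
    which(table$scenario %in% scenario_id)
  sub <- table
  sub$scenario <- table$scenario[keep]
  sub$params <- table$params[keep, , drop = FALSE]
  sub$stats <- table$stats[keep, , drop = FALSE]

  y <- sub$params[, param]
  if (stats::sd(y) == 0) {
    est <- rep(y[1], 3)
  } else {
    aug <- add_lda_axes_regression(sub, observed)
    qrf <- ranger::ranger(x = aug$X, y = y, num.trees = n_trees,
                          quantreg = TRUE, keep.inbag = TRUE,
                          num.threads = 1, seed = seed)
    est <- stats::predict(qrf, aug$newx, type = "quantiles",
                          quantiles = c(0.05, 0.5, 0.95),
                          num.threads = 1)$predictions[1, c(2, 1, 3)]
  }
  out <- list(param = param, median = est[1], q05 = est[2], q95 = est[3],
              median_ybp = generations_to_years(est[1], gen_time),
              q05_ybp = generations_to_years(est[2], gen_time),
              q95_ybp = generations_to_years(est[3], gen_time))
  class(out) <- "param_posterior"
  out
}

# LDA axes are class-label driven; for a single-scenario table they do not
# exist, so fall back to the raw statistics (internal)
add_lda_axes_regression <- function(sub, observed) {
  if (length(unique(sub$scenario)) >= 2L) {
    aug <- add_lda_axes(sub, observed)
    list(X = as.data.frame(aug$table$stats),
         newx = as.data.frame(as.list(aug$observed)))
  } else {
    obs <- as.numeric(observed)
    names(obs) <- colnames(sub$stats)
    list(X = as.data.frame(sub$stats), newx = as.data.frame(as.list(obs)))
  }
}

#' @export
print.param_posterior <- function(x, ...) {
  cat(sprintf("%s: median %.1f generations [%.1f, %.1f] (90%% interval)\n",
              x$param, x$median, x$q05, x$q95))
  cat(sprintf("  in years BP (x 2.5): %d [%d, %d]\n",
              x$median_ybp, x$q05_ybp, x$q95_ybp))
  invisible(x)
}

#' Persist / restore a reference table as text
#'
#' Writes the table rows (scenario id, parameters, summary statistics) as a
#' single TSV file at `<stem>.tsv` and the metadata (design, simulation
#' configuration, priors) as JSON at `<stem>.json`, keeping the artifact
#' reviewable as plain text. `read_reference_table` inverts the pair.
#'
#' @param table a `reference_table`.
#' @param stem file path without extension.
#' @return `write_reference_table`: `stem`, invisibly.
#'   `read_reference_table`: a `reference_table`.
#' @export
write_reference_table <- function(table, stem) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required to write reference-table metadata")
  df <- data.frame(scenario = table$scenario,
                   table$params, table$stats, check.names = FALSE)
  utils::write.table(df, paste0(stem, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- table$meta
  meta$simcfg <- unclass(meta$simcfg)
  jsonlite::write_json(
    list(meta = meta,
         param_names = colnames(table$params),
         stat_names = colnames(table$stats)),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_reference_table
#' @export
read_reference_table <- function(stem) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required to read reference-table metadata")
  df <- utils::read.table(paste0(stem, ".tsv"), sep = "\t", header = TRUE,
                          check.names = FALSE)
  info <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  tab <- list(scenario = as.integer(df$scenario),
              params = as.matrix(df[, info$param_names, drop = FALSE]),
              stats = as.matrix(df[, info$stat_names, drop = FALSE]),
              meta = info$meta)
  class(tab) <- "reference_table"
  tab
}

#' Convert generations to years before present
#'
#' Multiplies by the generation time and takes the floor, the convention
#' used for reporting cattle divergence dates (e.g. 2593 generations at
#' 2.5 years/generation is 6482 YBP, not 6483).
#'
#' @param g generations (scalar or vector).
#' @param gen_time generation time in years (default 2.5 for cattle).
#' @return Integer years before present.
#' @export
generations_to_years <- function(g, gen_time = 2.5) {
  as.integer(floor(g * gen_time))
}
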