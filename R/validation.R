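new_validation_report <- function(per_unit, unit, predictor, seed = NA_integer_,
                                  per_fold = NULL, scores = NULL) {
  structure(
    list(
      per_unit = per_unit, per_fold = per_fold, unit = unit,
      predictor = predictor_label(predictor), seed = seed, scores = scores
    ),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report> %s; %d %s unit(s)%s\n", x$predictor,
    nrow(x$per_unit), x$unit,
    if (is.na(x$seed)) "" else sprintf("; seed %d", x$seed)
  ))
  print(glance(x))
  invisible(x)
}

#' Tidy a validation report into per-unit metric rows
#'
#' @param x A `validation_report`.
#' @param ... Unused.
#' @return A tibble with one row per evaluation unit (drug or fold).
#' @exportS3Method generics::tidy
tidy.validation_report <- function(x, ...) x$per_unit

#' One-row summary of a validation report
#'
#' Median, interquartile range, mean and SD of every metric over the
#' report's evaluation units, plus counts of evaluated, skipped and
#' out-of-domain units.
#'
#' @param x A `validation_report`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @exportS3Method generics::glance
glance.validation_report <- function(x, ...) {
  metrics <- intersect(
    c("auroc", "auprc", "bedroc", "p_at_k", "r_at_k", "mcc_max", "f1_max", "bacc_max"),
    names(x$per_unit)
  )
  sums <- purrr::map(metrics, function(m) {
    v <- x$per_unit[[m]]
    tibble(
      "{m}_median" := median(v, na.rm = TRUE),
      "{m}_iqr" := stats::IQR(v, na.rm = TRUE),
      "{m}_mean" := mean(v, na.rm = TRUE),
      "{m}_sd" := sd(v, na.rm = TRUE)
    )
  })
  extra <- tibble(
    n_units = nrow(x$per_unit),
    n_skipped = sum(!x$per_unit$evaluable),
    n_outside_domain = sum(x$per_unit$outside_domain %||% FALSE)
  )
  dplyr::bind_cols(extra, !!!sums)
}

# Evaluate one held-out drug: scores come from `preds` (long tibble), labels
# from `truth_edges`, and only targets connected in training are evaluable.
evaluate_unit <- function(drug, preds, truth_edges, connected_targets,
                          all_targets, k, mask_targets = character()) {
  p <- preds[preds$query == drug, ]
  p <- p[match(all_targets, p$target), ]
  labels <- as.integer(all_targets %in% truth_edges$target[truth_edges$drug == drug])
  mask <- all_targets %in% connected_targets & !(all_targets %in% mask_targets)
  evaluate_ranking(p$score, labels, mask = mask, k = k)
}

#' Drug-wise leave-one-out cross-validation
#'
#' Holds out one drug at a time: all of its interactions are removed, the
#' network is rebuilt from the remaining drugs, the held-out drug is scored
#' de novo through its descriptors, and the prediction is evaluated against
#' the drug's true targets. Targets left with no training edge (disconnected
#' targets) can never be predicted and are masked from the metrics. Drugs
#' without any positive among the evaluable targets are reported but flagged
#' non-evaluable; drugs outside the predictor's application domain keep
#' their all-zero scores (worst-case ranking) and are flagged.
#'
#' @param ds An [interaction_dataset()].
#' @param predictor A configuration from [predictors] (not `predictor_nbi()`,
#'   which cannot score unseen drugs -- use [dti_holdout_kfold()]).
#' @param k Rank cut for P@k / R@k (default 20).
#' @param keep_scores Keep per-drug score tables in the report (for
#'   diagnostics; default `FALSE`).
#' @param labels Optional alternative truth edge table (`drug`, `target`)
#'   used for evaluation instead of `ds$edges`; training always uses
#'   `ds$edges`. This supports permutation-null controls where trained
#'   predictions are scored against shuffled labels.
#' @return A `validation_report` with one row per drug.
#' @export
loocv <- function(ds, predictor, k = 20, keep_scores = FALSE, labels = NULL) {
  if (length(ds$drugs) < 2) abort("leave-one-out needs at least 2 drugs")
  if (inherits(predictor, "nbi_predictor")) {
    abort("NBI cannot score drugs outside the network; use dti_holdout_kfold()")
  }
  truth <- if (is.null(labels)) ds$edges else as_tibble(labels)
  rows <- vector("list", length(ds$drugs))
  scores <- if (keep_scores) vector("list", length(ds$drugs)) else NULL
  for (i in seq_along(ds$drugs)) {
    d <- ds$drugs[i]
    train <- subset_drugs(ds, setdiff(ds$drugs, d))
    preds <- predict_targets(predictor, train, d)
    met <- evaluate_unit(d, preds, truth, unique(train$edges$target), ds$targets, k)
    rows[[i]] <- dplyr::bind_cols(
      tibble(
        unit = d,
        outside_domain = d %in% (attr(preds, "outside_domain") %||% character())
      ),
      met
    )
    if (keep_scores) scores[[i]] <- preds
  }
  per_unit <- dplyr::bind_rows(rows)
  per_unit$evaluable <- per_unit$n_pos > 0 & per_unit$n_neg > 0
  new_validation_report(per_unit, "drug", predictor,
    scores = if (keep_scores) setNames(scores, ds$drugs)
  )
}

# Deterministic near-equal partition of `ids` into `folds` groups after a
# seeded shuffle.
partition_ids <- function(ids, folds, seed) {
  if (folds > length(ids)) abort("more folds than units to partition")
  set.seed(seed)
  shuffled <- sample(ids)
  split(shuffled, rep_len(seq_len(folds), length(shuffled)))
}

#' Repeated drug-wise k-fold cross-validation
#'
#' Drugs are partitioned into near-equal folds (fresh seeded shuffle per
#' repeat; the per-repeat seed is `seed + repeat - 1`). For each fold, all
#' edges of the fold's drugs are removed, the fold's drugs are scored de
#' novo, and metrics are computed per drug; the per-fold value is the mean
#' over the fold's evaluable drugs.
#'
#' @inheritParams loocv
#' @param folds Number of folds (default 10).
#' @param repeats Number of repetitions (default 10).
#' @param seed Integer seed controlling all shuffles.
#' @return A `validation_report` with per-fold rows (per-drug rows are kept
#'   in `$per_drug` inside the report for the other granularity).
#' @export
repeated_kfold <- function(ds, predictor, folds = 10, repeats = 10, seed = 1,
                           k = 20, keep_scores = FALSE) {
  if (inherits(predictor, "nbi_predictor")) {
    abort("NBI cannot score drugs outside the network; use dti_holdout_kfold()")
  }
  drug_rows <- list()
  scores <- if (keep_scores) list() else NULL
  for (r in seq_len(repeats)) {
    parts <- partition_ids(ds$drugs, folds, seed + r - 1)
    for (f in seq_len(folds)) {
      test_drugs <- parts[[f]]
      train <- subset_drugs(ds, setdiff(ds$drugs, test_drugs))
      preds <- predict_targets(predictor, train, test_drugs)
      outside <- attr(preds, "outside_domain") %||% character()
      connected <- unique(train$edges$target)
      for (d in test_drugs) {
        met <- evaluate_unit(d, preds, ds$edges, connected, ds$targets, k)
        drug_rows[[length(drug_rows) + 1]] <- dplyr::bind_cols(
          tibble(
            repeat_ = r, fold = f, unit = d,
            outside_domain = d %in% outside
          ),
          met
        )
      }
      if (keep_scores) scores[[sprintf("r%df%d", r, f)]] <- preds
    }
  }
  per_drug <- dplyr::bind_rows(drug_rows)
  per_drug$evaluable <- per_drug$n_pos > 0 & per_drug$n_neg > 0
  per_fold <- per_drug |>
    dplyr::filter(.data$evaluable) |>
    dplyr::group_by(.data$repeat_, .data$fold) |>
    dplyr::summarise(
      n_drugs = dplyr::n(),
      dplyr::across(
        c("auroc", "auprc", "bedroc", "p_at_k", "r_at_k", "mcc_max", "f1_max", "bacc_max"),
        ~ mean(.x, na.rm = TRUE)
      ),
      .groups = "drop"
    ) |>
    dplyr::mutate(unit = sprintf("r%02df%02d", .data$repeat_, .data$fold), evaluable = TRUE)
  rep <- new_validation_report(per_fold, "fold", predictor, seed = seed, scores = scores)
  rep$per_drug <- per_drug
  rep
}

#' Repeated k-fold cross-validation over interactions (DTI holdout)
#'
#' Partitions the interaction edges (not the drugs) into folds, removes the
#' held-out edges from training, and evaluates each drug that lost at least
#' one edge against exactly those held-out edges. This is the scheme usable
#' by NBI, which cannot score drugs absent from the network: a drug losing
#' all of its edges in a fold is skipped for that fold (it is no longer in
#' the network), and a drug's retained training targets are masked, since
#' they are neither a novel positive nor a fair negative.
#'
#' @inheritParams repeated_kfold
#' @return A `validation_report` with per-fold rows and `$per_drug` detail.
#' @export
dti_holdout_kfold <- function(ds, predictor, folds = 10, repeats = 10, seed = 1,
                              k = 20, keep_scores = FALSE) {
  if (nrow(ds$edges) < folds) abort("fewer edges than folds")
  edge_ids <- seq_len(nrow(ds$edges))
  drug_rows <- list()
  scores <- if (keep_scores) list() else NULL
  for (r in seq_len(repeats)) {
    parts <- partition_ids(edge_ids, folds, seed + r - 1)
    for (f in seq_len(folds)) {
      held <- ds$edges[sort(parts[[f]]), ]
      train <- remove_edges(ds, held)
      in_net <- unique(train$edges$drug)
      qdrugs <- intersect(unique(held$drug), in_net)
      skipped <- setdiff(unique(held$drug), in_net)
      if (!length(qdrugs)) next
      train_q <- structure(
        list(drugs = in_net, targets = ds$targets, edges = train$edges),
        class = "interaction_dataset"
      )
      preds <- predict_targets(predictor, train_q, qdrugs)
      connected <- unique(train$edges$target)
      for (d in qdrugs) {
        met <- evaluate_unit(
          d, preds, held, connected, ds$targets, k,
          mask_targets = train$edges$target[train$edges$drug == d]
        )
        drug_rows[[length(drug_rows) + 1]] <- dplyr::bind_cols(
          tibble(repeat_ = r, fold = f, unit = d, outside_domain = FALSE),
          met
        )
      }
      if (length(skipped)) {
        inform(sprintf(
          "repeat %d fold %d: %d drug(s) lost all edges and were skipped",
          r, f, length(skipped)
        ))
      }
      if (keep_scores) scores[[sprintf("r%df%d", r, f)]] <- preds
    }
  }
  per_drug <- dplyr::bind_rows(drug_rows)
  per_drug$evaluable <- per_drug$n_pos > 0 & per_drug$n_neg > 0
  per_fold <- per_drug |>
    dplyr::filter(.data$evaluable) |>
    dplyr::group_by(.data$repeat_, .data$fold) |>
    dplyr::summarise(
      n_drugs = dplyr::n(),
      dplyr::across(
        c("auroc", "auprc", "bedroc", "p_at_k", "r_at_k", "mcc_max", "f1_max", "bacc_max"),
        ~ mean(.x, na.rm = TRUE)
      ),
      .groups = "drop"
    ) |>
    dplyr::mutate(unit = sprintf("r%02df%02d", .data$repeat_, .data$fold), evaluable = TRUE)
  rep <- new_validation_report(per_fold, "fold", predictor, seed = seed, scores = scores)
  rep$per_drug <- per_drug
  rep
}

#' Time-split (prospective) validation
#'
#' Builds the network exclusively from the training set and predicts targets
#' for every test drug, ignoring its test annotations during prediction.
#' Metrics are computed per test drug against its test edges; test drugs
#' with no positive on the shared target panel are skipped with a log
#' message. Inputs should come from [time_split()].
#'
#' @param train,test [interaction_dataset()] objects sharing a target panel.
#' @inheritParams loocv
#' @return A `validation_report` with one row per test drug.
#' @export
time_split_validate <- function(train, test, predictor, k = 20, keep_scores = FALSE) {
  drugs <- unique(test$edges$drug)
  no_pos <- setdiff(test$drugs, drugs)
  if (length(no_pos)) {
    inform(sprintf("%d test drug(s) have no positives and are skipped", length(no_pos)))
  }
  if (!length(drugs)) abort("no test drug has a positive on the shared target panel")
  preds <- predict_targets(predictor, train, drugs)
  outside <- attr(preds, "outside_domain") %||% character()
  connected <- unique(train$edges$target)
  rows <- purrr::map(drugs, function(d) {
    dplyr::bind_cols(
      tibble(unit = d, outside_domain = d %in% outside),
      evaluate_unit(d, preds, test$edges, connected, train$targets, k)
    )
  })
  per_unit <- dplyr::bind_rows(rows)
  per_unit$evaluable <- per_unit$n_pos > 0 & per_unit$n_neg > 0
  new_validation_report(per_unit, "drug", predictor,
    scores = if (keep_scores) list(preds)
  )
}

#' Similarity-cutoff grid sweep
#'
#' Re-runs a cross-validation harness over a grid of similarity cutoffs for
#' the SimSpread predictor and summarises each run, the standard procedure
#' for choosing the cutoff for a new descriptor.
#'
#' @param ds An [interaction_dataset()].
#' @param features Descriptor matrix covering all drugs.
#' @param alphas Cutoff grid (default 0, 0.05, ..., 1).
#' @param cv `"loo"` or `"kfold"`.
#' @param scheme,propagation,kind Passed to [predictor_simspread()].
#' @param folds,repeats,seed Passed to [repeated_kfold()] when
#'   `cv = "kfold"`.
#' @param k Rank cut for P@k / R@k.
#' @return A tibble with one row per cutoff (glance columns per run).
#' @export
alpha_sweep <- function(ds, features, alphas = seq(0, 1, by = 0.05),
                        cv = c("loo", "kfold"), scheme = "similarity",
                        propagation = "weighted", kind = "auto",
                        folds = 10, repeats = 1, seed = 1, k = 20) {
  cv <- match.arg(cv)
  purrr::map_dfr(alphas, function(a) {
    p <- predictor_simspread(features,
      alpha = a, scheme = scheme,
      propagation = propagation, kind = kind
    )
    rep <- if (cv == "loo") {
      loocv(ds, p, k = k)
    } else {
      repeated_kfold(ds, p, folds = folds, repeats = repeats, seed = seed, k = k)
    }
    dplyr::bind_cols(tibble(alpha = a), glance(rep))
  })
}
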