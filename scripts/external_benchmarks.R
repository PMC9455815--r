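#!/usr/bin/env Rscript
# Rerun the full benchmark suite on user-supplied external datasets.
#
# The published benchmark numbers (per-dataset LOO / 10x10-fold medians,
# time-split medians, top-250 scaffold and target counts) require the
# Yamanishi Enzyme / Ion Channel / GPCR / Nuclear Receptor sets, the Global
# set and a ChEMBL-derived time-split pair, none of which ship with this
# package. Point this script at local copies to reproduce the analysis:
#
#   Rscript scripts/external_benchmarks.R \
#     --data-dir path/with/{name}_interactions.tsv,{name}_ligands.smi \
#     --timesplit-train chembl24.tsv --timesplit-test chembl28.tsv \
#     --timesplit-smiles chembl_ligands.smi \
#     --out-dir results/external
#
# Each interactions file is a TSV edge list (drug, target); each .smi file
# holds "SMILES<tab>ID" lines covering the dataset's ligands.

suppressPackageStartupMessages(library(simspread))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(
  data_dir = NA, timesplit_train = NA, timesplit_test = NA,
  timesplit_smiles = NA, out_dir = "results/external", alpha = 0.2,
  folds = 10, repeats = 10, seed = 1
)
i <- 1
while (i <= length(args)) {
  key <- gsub("-", "_", sub("^--", "", args[i]))
  if (!key %in% names(opt)) stop("unknown option: ", args[i])
  opt[[key]] <- args[i + 1]
  i <- i + 2
}
opt$alpha <- as.numeric(opt$alpha)
opt$folds <- as.integer(opt$folds)
opt$repeats <- as.integer(opt$repeats)
opt$seed <- as.integer(opt$seed)
dir.create(opt$out_dir, recursive = TRUE, showWarnings = FALSE)

run_benchmark <- function(name, edges_path, smiles_path) {
  message("== dataset: ", name)
  ds <- read_interactions(edges_path)
  print(dataset_stats(ds))
  features <- compute_fingerprints(read_smiles(smiles_path), "ECFP4")
  methods <- list(
    simspread_sim = predictor_simspread(features, alpha = opt$alpha, scheme = "similarity"),
    simspread_bin = predictor_simspread(features,
      alpha = opt$alpha, scheme = "binary",
      propagation = "binary"
    ),
    sdtnbi = predictor_sdtnbi(features),
    knn1 = predictor_knn(features, k = 1)
  )
  for (m in names(methods)) {
    loo <- loocv(ds, methods[[m]])
    readr::write_tsv(tidy(loo), file.path(opt$out_dir, sprintf("%s_%s_loo.tsv", name, m)))
    kf <- repeated_kfold(ds, methods[[m]],
      folds = opt$folds, repeats = opt$repeats,
      seed = opt$seed
    )
    readr::write_tsv(tidy(kf), file.path(opt$out_dir, sprintf("%s_%s_kfold.tsv", name, m)))
    message(m, ": "); print(glance(loo))
  }
  nbi <- dti_holdout_kfold(ds, predictor_nbi(),
    folds = opt$folds, repeats = opt$repeats,
    seed = opt$seed
  )
  readr::write_tsv(tidy(nbi), file.path(opt$out_dir, sprintf("%s_nbi_dti_kfold.tsv", name)))
}

if (!is.na(opt$data_dir)) {
  edge_files <- list.files(opt$data_dir, pattern = "_interactions\\.tsv$", full.names = TRUE)
  for (f in edge_files) {
    name <- sub("_interactions\\.tsv$", "", basename(f))
    smi <- file.path(opt$data_dir, paste0(name, "_ligands.smi"))
    if (!file.exists(smi)) {
      message("skipping ", name, ": no ligand SMILES file")
      next
    }
    run_benchmark(name, f, smi)
  }
}

if (!is.na(opt$timesplit_train) && !is.na(opt$timesplit_test)) {
  message("== time-split validation")
  sp <- time_split(
    read_interactions(opt$timesplit_train),
    read_interactions(opt$timesplit_test)
  )
  smiles <- read_smiles(opt$timesplit_smiles)
  features <- compute_fingerprints(smiles, "ECFP4")
  methods <- list(
    simspread_sim = predictor_simspread(features, alpha = opt$alpha, scheme = "similarity"),
    simspread_bin = predictor_simspread(features,
      alpha = opt$alpha, scheme = "binary",
      propagation = "binary"
    ),
    sdtnbi = predictor_sdtnbi(features),
    knn1 = predictor_knn(features, k = 1)
  )
  pooled <- list()
  for (m in names(methods)) {
    rep <- time_split_validate(sp$train, sp$test, methods[[m]], keep_scores = TRUE)
    readr::write_tsv(tidy(rep), file.path(opt$out_dir, sprintf("timesplit_%s.tsv", m)))
    message(m, ": "); print(glance(rep))
    pooled[[m]] <- rep$scores[[1]]
  }
  # exploration analysis: scaffold and target diversity of the top-L
  # pooled predictions per method, including the top-250 snapshot
  train_scaf <- murcko_scaffold(smiles[intersect(names(smiles), sp$train$drugs)])
  query_ids <- unique(sp$test$edges$drug)
  query_scaf <- murcko_scaffold(smiles[intersect(names(smiles), query_ids)])
  for (m in names(pooled)) {
    curves <- diversity_curves(pooled[[m]], train_scaf, query_scaf,
      L_grid = seq(10, 1000, by = 10)
    )
    readr::write_tsv(curves, file.path(opt$out_dir, sprintf("diversity_%s.tsv", m)))
    top250 <- curves[curves$L == 250, ]
    message(sprintf(
      "%s top-250: %d known / %d novel scaffolds, %d targets",
      m, top250$n_known_scaffolds, top250$n_novel_scaffolds, top250$n_unique_targets
    ))
  }
  # application-domain fraction of the test ligands at the chosen cutoff
  fp_q <- features[intersect(rownames(features), query_ids), , drop = FALSE]
  fp_d <- features[intersect(rownames(features), sp$train$drugs), , drop = FALSE]
  s <- similarity_matrix(fp_q, fp_d)
  outside <- mean(apply(s, 1, max) < opt$alpha) * 100
  message(sprintf("ligands outside the application domain: %.1f%%", outside))
}
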