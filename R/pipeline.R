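#' Pipeline configuration
#'
#' Collects every tunable of the mesh -> spectrum -> features -> embed ->
#' cluster -> descriptors -> tests pipeline, validated up front. A single
#' global `seed` fans out to per-stage seeds through a fixed derivation, so
#' one integer reproduces a whole run.
#'
#' @param probe probe radius, angstrom (default 1.4).
#' @param resolution meshing grid spacing, angstrom (default 0.5).
#' @param n_eigenpairs Laplace-Beltrami eigenpairs per molecule (default
#'   32).
#' @param sample_size curvature-weighted sample size (default 200).
#' @param curvature_variant `"normal"` or `"literal"`.
#' @param canonicalize row canonicalization of the feature matrices:
#'   `"column_sorted"` (default; each eigenvector column's sampled values
#'   sorted descending — stable across meshes without vertex
#'   correspondence) or `"curvature"` (rows follow the curvature-ranked
#'   sampled vertices).
#' @param model embedding model: `"dbn"`, `"cae"`, `"vae"`, `"aae"`, or
#'   `"none"` (cluster the standardized features directly).
#' @param latent_dim latent dimension (default 32).
#' @param epochs training epochs (per layer for the DBN).
#' @param K_values cluster counts (default 16, 32, 64).
#' @param seed global seed.
#' @param joint_lambda if positive, run joint reconstruction + clustering
#'   fine-tuning with this weight after pretraining (autoencoders only).
#' @param balaban,mti,xu descriptor variant flags (`"printed"` or
#'   `"standard"`).
#' @param quarantine_threshold abort if more than this fraction of
#'   molecules fails meshing/featurization (default 0.5).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(probe = 1.4, resolution = 0.5,
                            n_eigenpairs = 32, sample_size = 200,
                            curvature_variant = "normal",
                            canonicalize = c("column_sorted", "curvature"),
                            model = c("dbn", "cae", "vae", "aae", "none"),
                            latent_dim = 32, epochs = NULL,
                            K_values = c(16, 32, 64), seed = 7,
                            joint_lambda = 0,
                            balaban = "printed", mti = "printed",
                            xu = "printed", quarantine_threshold = 0.5) {
  stopifnot(probe >= 0, resolution > 0, n_eigenpairs >= 1,
            sample_size >= 1, latent_dim >= 1, joint_lambda >= 0,
            all(K_values >= 2))
  model <- match.arg(model)
  canonicalize <- match.arg(canonicalize)
  epochs <- epochs %||% if (model == "dbn") 200 else 30
  structure(
    list(probe = probe, resolution = resolution,
         n_eigenpairs = n_eigenpairs, sample_size = sample_size,
         curvature_variant = curvature_variant,
         canonicalize = canonicalize, model = model,
         latent_dim = latent_dim, epochs = epochs,
         K_values = as.integer(K_values), seed = as.integer(seed),
         joint_lambda = joint_lambda, balaban = balaban, mti = mti,
         xu = xu, quarantine_threshold = quarantine_threshold),
    class = "pipeline_config"
  )
}

canonicalize_features <- function(feat, how) {
  if (how == "column_sorted") {
    feat$matrix <- apply(feat$matrix, 2, sort, decreasing = TRUE)
  }
  feat
}

#' Run the full spectral-geometry clustering pipeline
#'
#' Executes, in order: SAS meshing, Laplace-Beltrami spectral
#' decomposition, curvature-weighted sampling and feature-matrix
#' construction, feature standardization, embedding (DBN or an
#' autoencoder), k-means at each requested `K` with the six validity
#' indices, topological descriptors on the heavy-atom graphs, and the
#' three nonparametric descriptor-association tests. Per-molecule failures
#' (meshing, featurization, descriptor computation) are quarantined with
#' their reasons; the run aborts only if more than the configured fraction
#' of molecules is lost.
#'
#' @param mols list of [mol_record()]s, or a tibble with a `mol`
#'   list-column (e.g. [make_synthetic_library()]), or a structure file
#'   path readable by [read_structures()].
#' @param config a [pipeline_config()].
#' @param output_dir optional directory; when given, meshes (PLY),
#'   eigenvalues, features manifest, labels, metric/descriptor/test tables
#'   (CSV) and a JSON run manifest are written there.
#' @param format file format when `mols` is a path.
#' @return An object of class `molspec_run`: list with `features`,
#'   `dataset`, `model`, `latent`, `assignments` (one [kmeans_fit()] per
#'   K), `metrics`, `descriptors`, `tests`, `quarantine`, `config`,
#'   `manifest`.
#' @export
run_pipeline <- function(mols, config = pipeline_config(),
                         output_dir = NULL, format = "sdf") {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(mols) && length(mols) == 1) {
    mols <- read_structures(mols, format = format)
  }
  if (is.data.frame(mols)) mols <- mols$mol
  if (inherits(mols, "mol_record")) mols <- list(mols)
  n_input <- length(mols)
  if (n_input == 0) stop("no input molecules")
  ids <- vapply(mols, function(m) m$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate molecule ids")

  quarantine <- tibble::tibble(id = character(0), stage = character(0),
                               reason = character(0))
  meshes <- list()
  features <- list()
  eigenvalues <- list()
  kept <- logical(n_input)
  for (i in seq_len(n_input)) {
    mol <- mols[[i]]
    res <- tryCatch({
      mesh <- build_sas_mesh(mol, probe = config$probe,
                             resolution = config$resolution)
      lap <- assemble_laplacian(mesh)
      spec <- eigendecompose(lap, N = min(config$n_eigenpairs,
                                          nrow(mesh$vertices)))
      curv <- mean_curvature(mesh, lap, variant = config$curvature_variant)
      idx <- weighted_sample(curv, k = config$sample_size,
                             seed = derive_seed(config$seed,
                                                paste0("sample_", mol$id)))
      feat <- build_feature_matrix(spec, idx, curv, molecule_id = mol$id,
                                   pad_to = config$sample_size)
      list(mesh = mesh, feat = canonicalize_features(feat,
                                                     config$canonicalize),
           values = spec$values)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      quarantine <- dplyr::bind_rows(quarantine, tibble::tibble(
        id = mol$id, stage = "features", reason = conditionMessage(res)
      ))
    } else {
      kept[i] <- TRUE
      meshes[[mol$id]] <- res$mesh
      features[[mol$id]] <- res$feat
      eigenvalues[[mol$id]] <- res$values
    }
  }
  if (sum(kept) < n_input * (1 - config$quarantine_threshold) ||
      sum(kept) == 0) {
    stop("pipeline aborted: only ", sum(kept), " of ", n_input,
         " molecules survived featurization")
  }
  mols_kept <- mols[kept]

  dataset <- feature_dataset(features)
  embed_seed <- derive_seed(config$seed, "embed")
  if (config$model == "none") {
    model <- NULL
    Z <- dataset$X
  } else if (config$model == "dbn") {
    model <- dbn_train(dataset$X,
                       layer_sizes = c(512, 128, config$latent_dim),
                       epochs = config$epochs, seed = embed_seed)
    Z <- dbn_encode(model, dataset$X)
  } else {
    model <- train_autoencoder(dataset, kind = config$model,
                               latent_dim = config$latent_dim,
                               epochs = config$epochs, seed = embed_seed)
    if (config$joint_lambda > 0) {
      init_fit <- kmeans_fit(encode_latent(model, dataset$X),
                             K = min(config$K_values),
                             seed = derive_seed(config$seed, "joint_init"))
      model <- joint_finetune(model, dataset, init_fit,
                              lambda = config$joint_lambda,
                              seed = embed_seed)
    }
    Z <- encode_latent(model, dataset$X)
  }

  assignments <- list()
  metrics <- list()
  for (K in config$K_values) {
    if (K > nrow(Z)) {
      warning("skipping K = ", K, ": more clusters than molecules")
      next
    }
    fit <- kmeans_fit(Z, K, seed = derive_seed(config$seed,
                                               paste0("kmeans", K)))
    assignments[[as.character(K)]] <- fit
    metrics[[as.character(K)]] <- dplyr::bind_cols(
      tibble::tibble(K = K, wcss = fit$wcss), score_clustering(Z, fit)
    )
  }
  metrics <- dplyr::bind_rows(metrics)

  desc_rows <- list()
  for (mol in mols_kept) {
    r <- tryCatch(descriptor_table(list(mol), balaban = config$balaban,
                                   mti = config$mti, xu = config$xu),
                  error = function(e) e)
    if (inherits(r, "error")) {
      quarantine <- dplyr::bind_rows(quarantine, tibble::tibble(
        id = mol$id, stage = "descriptors", reason = conditionMessage(r)
      ))
    } else {
      desc_rows[[mol$id]] <- r
    }
  }
  descriptors <- dplyr::bind_rows(desc_rows)

  tests <- NULL
  if (nrow(descriptors) > 0 && length(assignments) > 0) {
    assign_tbl <- dplyr::bind_rows(lapply(names(assignments), function(Kn) {
      labs <- assignments[[Kn]]$labels
      tibble::tibble(id = dataset$ids, K = as.integer(Kn), cluster = labs)
    }))
    assign_tbl <- assign_tbl[assign_tbl$id %in% descriptors$id, ]
    drop_cols <- vapply(descriptors[-1], function(v) {
      length(unique(v)) == 1
    }, logical(1))
    test_desc <- descriptors[c(TRUE, !drop_cols)]
    if (ncol(test_desc) > 1) {
      tests <- test_report(test_desc, assign_tbl)
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("molspec")),
    seed = config$seed,
    config = unclass(config),
    n_input = n_input, n_kept = sum(kept),
    hashes = list(
      features = rlang::hash(features),
      latent = rlang::hash(Z),
      metrics = rlang::hash(metrics)
    )
  )

  run <- structure(
    list(features = features, eigenvalues = eigenvalues,
         dataset = dataset, model = model, latent = Z,
         assignments = assignments, metrics = metrics,
         descriptors = descriptors, tests = tests,
         quarantine = quarantine, config = config, manifest = manifest),
    class = "molspec_run"
  )
  if (!is.null(output_dir)) write_run(run, meshes, output_dir)
  run
}

write_run <- function(run, meshes, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  mesh_dir <- file.path(output_dir, "meshes")
  dir.create(mesh_dir, showWarnings = FALSE)
  for (id in names(meshes)) {
    write_mesh(meshes[[id]], file.path(mesh_dir, paste0(id, ".ply")))
  }
  eig <- dplyr::bind_rows(lapply(names(run$eigenvalues), function(mol_id) {
    vals <- run$eigenvalues[[mol_id]]
    tibble::tibble(id = mol_id, index = seq_along(vals), eigenvalue = vals)
  }))
  utils::write.csv(eig, file.path(output_dir, "eigenvalues.csv"),
                   row.names = FALSE)
  utils::write.csv(run$metrics, file.path(output_dir, "metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(run$metrics, file.path(output_dir, "metrics.json"),
                       dataframe = "rows", digits = NA)
  if (nrow(run$descriptors) > 0) {
    utils::write.csv(run$descriptors,
                     file.path(output_dir, "descriptors.csv"),
                     row.names = FALSE)
  }
  if (!is.null(run$tests)) {
    utils::write.csv(run$tests, file.path(output_dir, "tests.csv"),
                     row.names = FALSE)
    jsonlite::write_json(run$tests, file.path(output_dir, "tests.json"),
                         dataframe = "rows", digits = NA)
  }
  labels <- dplyr::bind_rows(lapply(names(run$assignments), function(Kn) {
    labs <- run$assignments[[Kn]]$labels
    tibble::tibble(id = run$dataset$ids, K = as.integer(Kn),
                   cluster = labs)
  }))
  utils::write.csv(labels, file.path(output_dir, "labels.csv"),
                   row.names = FALSE)
  if (nrow(run$quarantine) > 0) {
    utils::write.csv(run$quarantine,
                     file.path(output_dir, "quarantine.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(run$manifest,
                       file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(output_dir)
}

#' @export
print.molspec_run <- function(x, ...) {
  cat(sprintf(
    "<molspec_run> %d molecules (%d quarantined), model = %s, K = %s\n",
    length(x$features), nrow(x$quarantine), x$config$model,
    paste(x$config$K_values, collapse = "/")
  ))
  if (nrow(x$metrics) > 0) print(x$metrics)
  invisible(x)
}

#' @rdname run_pipeline
#' @param x a `molspec_run`.
#' @param ... unused.
#' @export
glance.molspec_run <- function(x, ...) {
  tibble::tibble(
    n_molecules = length(x$features),
    n_quarantined = nrow(x$quarantine),
    model = x$config$model,
    seed = x$config$seed
  )
}
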