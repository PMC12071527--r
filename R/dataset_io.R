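# Containers for aligned multi-sensor feature tables, CSV round-tripping,
# and the train/test partition schemes used in the analyses.

#' A single-modality spectral feature block
#'
#' A numeric observations x features matrix with unique sample IDs as row
#' names and feature labels as column names. FTIR blocks additionally carry
#' the numeric wavenumber axis (strictly monotone); MSI/MSIF blocks use
#' band-by-statistic feature labels.
#'
#' @param matrix numeric matrix, no missing values; row names are sample IDs
#' @param modality block label, e.g. "FTIR", "MSI", "MSIF"
#' @param wavenumbers optional numeric wavenumber axis (cm-1), one per column,
#'   strictly monotone; required for range restriction and smoothing checks
#' @return an object of class `spectral_block`
#' @export
spectral_block <- function(matrix, modality, wavenumbers = NULL) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("`matrix` must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(matrix)) stop("spectral block contains missing values", call. = FALSE)
  if (is.null(rownames(matrix)) || anyDuplicated(rownames(matrix))) {
    stop("`matrix` must have unique sample IDs as row names", call. = FALSE)
  }
  if (is.null(colnames(matrix))) {
    stop("`matrix` must have feature labels as column names", call. = FALSE)
  }
  if (!is.null(wavenumbers)) {
    if (length(wavenumbers) != ncol(matrix)) {
      stop("`wavenumbers` length must match the feature count", call. = FALSE)
    }
    d <- diff(wavenumbers)
    if (!(all(d > 0) || all(d < 0))) {
      stop("`wavenumbers` must be strictly monotone", call. = FALSE)
    }
  }
  structure(list(modality = modality, matrix = matrix,
                 wavenumbers = wavenumbers),
            class = "spectral_block")
}

#' @export
print.spectral_block <- function(x, ...) {
  cat(sprintf("<spectral_block> %s: %d samples x %d features\n",
              x$modality, nrow(x$matrix), ncol(x$matrix)))
  if (!is.null(x$wavenumbers)) {
    cat(sprintf("  wavenumber axis %.4f..%.4f cm-1\n",
                x$wavenumbers[1], x$wavenumbers[length(x$wavenumbers)]))
  }
  invisible(x)
}

#' @export
dim.spectral_block <- function(x) dim(x$matrix)

#' Sample IDs of a block or dataset
#' @param x a `spectral_block` or `multimodal_dataset`
#' @return character vector of sample IDs in storage order
#' @export
sample_ids <- function(x) {
  if (inherits(x, "spectral_block")) return(rownames(x$matrix))
  if (inherits(x, "multimodal_dataset")) return(x$metadata$sample_id)
  stop("unsupported object", call. = FALSE)
}

#' An aligned multi-sensor dataset
#'
#' Bundles one or more spectral blocks with a sample metadata table. All
#' blocks must share identical sample IDs in identical order, and the
#' metadata must cover exactly those IDs. Metadata columns: `sample_id`,
#' `meat_type`, `condition`, `temperature` (degrees C), `time` (h), `batch`,
#' `replicate`, and the regression target `tvc` (log CFU/g).
#'
#' @param blocks named list of [spectral_block()] objects
#' @param metadata data.frame of per-sample metadata
#' @return an object of class `multimodal_dataset`
#' @export
multimodal_dataset <- function(blocks, metadata) {
  required <- c("sample_id", "condition", "temperature", "time", "batch",
                "replicate", "tvc")
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols)) {
    stop("metadata is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(metadata$sample_id)) {
    stop("metadata sample IDs must be unique", call. = FALSE)
  }
  if (any(metadata$tvc < 0)) stop("`tvc` must be non-negative", call. = FALSE)
  if (length(blocks) == 0L || is.null(names(blocks))) {
    stop("`blocks` must be a nonempty named list", call. = FALSE)
  }
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    stopifnot(inherits(b, "spectral_block"))
    if (!identical(rownames(b$matrix), metadata$sample_id)) {
      stop(sprintf("block '%s' sample IDs do not match the metadata order", nm),
           call. = FALSE)
    }
  }
  structure(list(blocks = blocks, metadata = metadata),
            class = "multimodal_dataset")
}

#' @export
print.multimodal_dataset <- function(x, ...) {
  cat(sprintf("<multimodal_dataset> %d samples, %d modalities\n",
              nrow(x$metadata), length(x$blocks)))
  for (nm in names(x$blocks)) {
    cat(sprintf("  %-5s %d features\n", nm, ncol(x$blocks[[nm]]$matrix)))
  }
  cat(sprintf("  conditions: %s; batches: %s; TVC %.2f..%.2f log CFU/g\n",
              paste(unique(x$metadata$condition), collapse = ", "),
              paste(sort(unique(x$metadata$batch)), collapse = ", "),
              min(x$metadata$tvc), max(x$metadata$tvc)))
  invisible(x)
}

#' Subset a dataset by sample ID
#'
#' Keeps the given IDs, in the given order, across every block and the
#' metadata.
#'
#' @param dataset a [multimodal_dataset()]
#' @param ids character vector of sample IDs (must all exist)
#' @return a [multimodal_dataset()]
#' @export
subset_dataset <- function(dataset, ids) {
  stopifnot(inherits(dataset, "multimodal_dataset"))
  idx <- match(ids, dataset$metadata$sample_id)
  if (anyNA(idx)) stop("unknown sample IDs in `ids`", call. = FALSE)
  blocks <- lapply(dataset$blocks, function(b) {
    spectral_block(b$matrix[idx, , drop = FALSE], b$modality, b$wavenumbers)
  })
  multimodal_dataset(blocks, dataset$metadata[idx, , drop = FALSE])
}

#' Extract plain feature matrices from a dataset
#' @param dataset a [multimodal_dataset()]
#' @param modalities block names to extract (default all, in storage order)
#' @return named list of numeric matrices
#' @export
block_matrices <- function(dataset, modalities = names(dataset$blocks)) {
  missing_mod <- setdiff(modalities, names(dataset$blocks))
  if (length(missing_mod)) {
    stop("modalities not present: ", paste(missing_mod, collapse = ", "),
         call. = FALSE)
  }
  lapply(stats::setNames(modalities, modalities),
         function(m) dataset$blocks[[m]]$matrix)
}

fmt17 <- function(x) sprintf("%.17g", x)

#' Write a dataset to per-modality CSV files
#'
#' One CSV per modality (`<modality>.csv`, sample_id column first, features
#' serialised with 17 significant digits so the round trip is exact) plus
#' `metadata.csv`.
#'
#' @param dataset a [multimodal_dataset()]
#' @param dir output directory, created if needed
#' @return invisibly, the named vector of file paths written
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "multimodal_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(metadata = file.path(dir, "metadata.csv"))
  meta <- dataset$metadata
  meta$tvc <- fmt17(meta$tvc)
  data.table::fwrite(meta, paths[["metadata"]])
  for (nm in names(dataset$blocks)) {
    b <- dataset$blocks[[nm]]
    df <- data.table::as.data.table(apply(b$matrix, 2, fmt17))
    data.table::setnames(df, colnames(b$matrix))
    df <- cbind(data.table::data.table(sample_id = rownames(b$matrix)), df)
    p <- file.path(dir, paste0(nm, ".csv"))
    data.table::fwrite(df, p)
    paths[[nm]] <- p
  }
  invisible(paths)
}

#' Load an aligned dataset from per-modality CSV files
#'
#' Reads the metadata table and the requested modality files, then takes the
#' strict inner join on `sample_id` (rows are ordered by sorted ID, so the
#' result is invariant to row order in the files). Rows present in the
#' metadata but missing from any requested block are dropped with a warning
#' stating the count.
#'
#' @param block_paths named character vector of modality CSV paths; names are
#'   the modality labels (FTIR blocks, recognised by the name "FTIR", get a
#'   numeric wavenumber axis parsed from the column names)
#' @param metadata_path path of the metadata CSV
#' @return a [multimodal_dataset()]
#' @export
load_dataset <- function(block_paths, metadata_path) {
  if (is.null(names(block_paths)) || any(names(block_paths) == "")) {
    stop("`block_paths` must be named by modality", call. = FALSE)
  }
  for (p in c(block_paths, metadata_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  # read all fields as text, then convert through strtod: correctly rounded,
  # so 17-significant-digit serialisation round-trips bit-exactly
  meta <- as.data.frame(data.table::fread(metadata_path, header = TRUE,
                                          colClasses = "character"))
  meta[] <- lapply(meta, utils::type.convert, as.is = TRUE)
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample IDs in metadata", call. = FALSE)
  }
  raw <- lapply(block_paths, function(p) {
    df <- as.data.frame(data.table::fread(p, header = TRUE,
                                          colClasses = "character"))
    if (anyDuplicated(df$sample_id)) {
      stop("duplicate sample IDs in ", p, call. = FALSE)
    }
    df
  })
  common <- Reduce(intersect, c(list(meta$sample_id),
                                lapply(raw, function(d) d$sample_id)))
  if (length(common) == 0L) {
    stop("no sample IDs shared by all input files", call. = FALSE)
  }
  dropped <- length(meta$sample_id) - length(common)
  if (dropped > 0L) {
    warning(sprintf("dropped %d metadata row(s) missing from at least one block",
                    dropped), call. = FALSE)
  }
  ids <- sort(common)
  meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  blocks <- lapply(stats::setNames(names(raw), names(raw)), function(nm) {
    df <- raw[[nm]]
    m <- as.matrix(df[match(ids, df$sample_id), setdiff(names(df), "sample_id"),
                      drop = FALSE])
    mode(m) <- "numeric"
    if (anyNA(m)) stop("non-numeric feature values in block '", nm, "'",
                       call. = FALSE)
    rownames(m) <- ids
    wn <- NULL
    if (toupper(nm) == "FTIR") {
      wn <- suppressWarnings(as.numeric(colnames(m)))
      if (anyNA(wn)) stop("FTIR column names must be numeric wavenumbers",
                          call. = FALSE)
    }
    spectral_block(m, modality = nm, wavenumbers = wn)
  })
  multimodal_dataset(blocks, meta)
}

#' Build a train/test partition plan
#'
#' `batch_on_batch` trains on batch 1 of the selected condition(s) and tests
#' on batch 2, with one auxiliary test set per condition in the dataset so a
#' model can also be scored on conditions it was not trained on.
#' `combined_conditions` pools batch 1 of every condition for training and
#' keeps the per-condition batch-2 test sets separate for per-condition
#' reporting. `explicit` takes user-supplied ID vectors. Plans are pure
#' functions of the dataset and scheme.
#'
#' @param dataset a [multimodal_dataset()]
#' @param scheme one of `"batch_on_batch"`, `"combined_conditions"`, `"explicit"`
#' @param conditions condition labels to train on (batch_on_batch only;
#'   default: all conditions present)
#' @param train_ids,test_ids explicit ID vectors (explicit scheme only)
#' @return an object of class `partition_plan` with elements `scheme`,
#'   `train_ids`, `test_ids` and `test_sets` (named list of per-condition
#'   test-ID vectors)
#' @export
make_partition <- function(dataset,
                           scheme = c("batch_on_batch", "combined_conditions",
                                      "explicit"),
                           conditions = NULL,
                           train_ids = NULL, test_ids = NULL) {
  stopifnot(inherits(dataset, "multimodal_dataset"))
  scheme <- match.arg(scheme)
  meta <- dataset$metadata
  all_conditions <- unique(meta$condition)
  if (scheme == "explicit") {
    if (is.null(train_ids) || is.null(test_ids)) {
      stop("explicit scheme needs `train_ids` and `test_ids`", call. = FALSE)
    }
    if (length(intersect(train_ids, test_ids))) {
      stop("train and test IDs overlap", call. = FALSE)
    }
    unknown <- setdiff(c(train_ids, test_ids), meta$sample_id)
    if (length(unknown)) stop("unknown sample IDs in the plan", call. = FALSE)
    test_sets <- split(test_ids,
                       meta$condition[match(test_ids, meta$sample_id)])
    plan <- list(scheme = scheme, train_ids = train_ids, test_ids = test_ids,
                 test_sets = test_sets)
    class(plan) <- "partition_plan"
    return(plan)
  }
  if (!all(c(1L, 2L) %in% unique(meta$batch))) {
    stop("batch-based schemes need both batch 1 and batch 2 in the dataset",
         call. = FALSE)
  }
  train_conditions <- if (scheme == "combined_conditions") {
    all_conditions
  } else {
    conditions %||% all_conditions
  }
  unknown <- setdiff(train_conditions, all_conditions)
  if (length(unknown)) {
    stop("unknown condition label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  train_ids <- meta$sample_id[meta$batch == 1L &
                                meta$condition %in% train_conditions]
  test_sets <- lapply(stats::setNames(all_conditions, all_conditions),
                      function(cc) {
                        meta$sample_id[meta$batch == 2L & meta$condition == cc]
                      })
  test_ids <- meta$sample_id[meta$batch == 2L &
                               meta$condition %in% train_conditions]
  if (length(train_ids) == 0L || length(test_ids) == 0L) {
    stop("empty train or test partition", call. = FALSE)
  }
  plan <- list(scheme = scheme, train_ids = train_ids, test_ids = test_ids,
               test_sets = test_sets, conditions = train_conditions)
  class(plan) <- "partition_plan"
  plan
}

#' @export
print.partition_plan <- function(x, ...) {
  cat(sprintf("<partition_plan> %s: %d train / %d test\n", x$scheme,
              length(x$train_ids), length(x$test_ids)))
  for (nm in names(x$test_sets)) {
    cat(sprintf("  test[%s]: %d\n", nm, length(x$test_sets[[nm]])))
  }
  invisible(x)
}

#' Serialise / restore a partition plan as JSON
#' @param plan a `partition_plan`
#' @param path optional file path; if omitted the JSON string is returned
#' @return JSON string (or, for the reader, a `partition_plan`)
#' @export
partition_to_json <- function(plan, path = NULL) {
  stopifnot(inherits(plan, "partition_plan"))
  js <- jsonlite::toJSON(unclass(plan), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname partition_to_json
#' @param json JSON string or file path produced by [partition_to_json()]
#' @export
partition_from_json <- function(json) {
  plan <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  plan$test_sets <- as.list(plan$test_sets)
  class(plan) <- "partition_plan"
  plan
}
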