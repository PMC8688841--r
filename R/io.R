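#' Write a domain collection to the plain-text exchange layout
#'
#' One CSV per domain (feature columns `f1..fF` plus a `label` column when
#' labels are present) and a `manifest.json` describing the grid, class
#' count, label mapping and feature layout. The same layout is read back by
#' [read_domain_collection()], so synthetic data round-trips through disk as
#' if it were real extracted-feature data.
#'
#' @param coll A [domain_collection()].
#' @param dir Output directory (created if missing).
#' @param n_electrodes,n_bands Feature layout recorded in the manifest;
#'   their product must equal `n_features`.
#' @param label_mapping Optional named integer vector (raw -> contiguous)
#'   recorded in the manifest.
#' @return `dir`, invisibly.
#' @export
write_domain_collection <- function(coll, dir, n_electrodes = 62L, n_bands = 5L,
                                    label_mapping = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_features <- ncol(coll$domains[[1L]]$features)
  if (n_electrodes * n_bands != n_features) {
    stopf("layout %d x %d does not match n_features = %d", n_electrodes,
          n_bands, n_features, class = "msmda_config_error")
  }
  entries <- list()
  for (s in seq_len(coll$n_subjects)) {
    for (k in seq_len(coll$n_sessions)) {
      d <- collection_domain(coll, s, k)
      fname <- sprintf("s%02d_k%d.csv", s, k)
      df <- as.data.frame(d$features)
      names(df) <- paste0("f", seq_len(ncol(df)))
      if (!is.null(d$labels)) df$label <- d$labels
      utils::write.csv(df, file.path(dir, fname), row.names = FALSE)
      entries[[length(entries) + 1L]] <- list(
        subject_index = s, session_index = k, path = fname,
        n_samples = nrow(d$features), labelled = !is.null(d$labels)
      )
    }
  }
  manifest <- list(
    format = "msmda_collection", version = 1L,
    n_subjects = coll$n_subjects, n_sessions = coll$n_sessions,
    n_classes = coll$n_classes,
    feature_layout = list(n_electrodes = as.integer(n_electrodes),
                          n_bands = as.integer(n_bands),
                          n_features = n_features,
                          column_order = "channel_major_band_minor"),
    label_mapping = if (is.null(label_mapping)) NULL else as.list(label_mapping),
    domains = entries
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Read a domain collection from the exchange layout
#'
#' @param path Directory containing `manifest.json`, or the manifest path.
#' @return A [domain_collection()]; every domain is validated against the
#'   manifest (row counts, label range vs `n_classes`).
#' @export
read_domain_collection <- function(path) {
  manifest_path <- if (dir.exists(path)) file.path(path, "manifest.json") else path
  if (!file.exists(manifest_path)) {
    stopf("no manifest at '%s'", manifest_path, class = "msmda_io_error")
  }
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  dir <- dirname(manifest_path)
  if (!identical(man$format, "msmda_collection")) {
    stopf("'%s' is not a collection manifest", manifest_path,
          class = "msmda_io_error")
  }
  nf <- man$feature_layout$n_features
  domains <- vector("list", nrow(man$domains))
  order_key <- order(man$domains$subject_index, man$domains$session_index)
  idx <- 0L
  for (r in order_key) {
    e <- man$domains[r, ]
    fp <- file.path(dir, e$path)
    if (!file.exists(fp)) {
      stopf("domain file missing: '%s'", fp, class = "msmda_io_error")
    }
    df <- utils::read.csv(fp)
    has_label <- "label" %in% names(df)
    X <- as.matrix(df[, setdiff(names(df), "label"), drop = FALSE])
    if (ncol(X) != nf) {
      stopf("'%s' has %d feature columns, manifest says %d", fp, ncol(X), nf,
            class = "msmda_schema_error")
    }
    if (nrow(X) != e$n_samples) {
      stopf("'%s' has %d rows, manifest says %d", fp, nrow(X), e$n_samples,
            class = "msmda_schema_error")
    }
    dimnames(X) <- NULL
    d <- domain_dataset(X,
                        labels = if (has_label) df$label else NULL,
                        domain_id = sprintf("s%02d/k%d", e$subject_index,
                                            e$session_index))
    idx <- idx + 1L
    domains[[idx]] <- validate_domain(d, man$n_classes)
  }
  domain_collection(domains, man$n_subjects, man$n_sessions, man$n_classes)
}

#' Write a multi-source task to the exchange layout
#'
#' Sources become subjects `1..N` and the target subject `N + 1`, all in
#' session 1; [read_multisource_task()] reverses the mapping.
#'
#' @param task A [multisource_task()].
#' @param dir Output directory.
#' @param n_electrodes,n_bands Feature layout for the manifest.
#' @return `dir`, invisibly.
#' @export
write_multisource_task <- function(task, dir, n_electrodes = 62L, n_bands = 5L) {
  N <- length(task$sources)
  coll <- domain_collection(c(task$sources, list(task$target)),
                            n_subjects = N + 1L, n_sessions = 1L,
                            n_classes = task$n_classes)
  write_domain_collection(coll, dir, n_electrodes, n_bands)
}

#' Read a multi-source task written by [write_multisource_task()]
#'
#' @param path Directory or manifest path.
#' @return A [multisource_task()]: subjects `1..S-1` as sources, subject `S`
#'   as target.
#' @export
read_multisource_task <- function(path) {
  coll <- read_domain_collection(path)
  build_cross_subject_tasks(coll)[[1L]]
}

#' Save a trained model to a single-file checkpoint
#'
#' The checkpoint embeds the weights, the architecture and the training
#' configuration, so [load_model()] restores a fully usable fit.
#'
#' @param fit An `msmda_fit`.
#' @param path Output file path (`.rds`).
#' @return `path`, invisibly.
#' @export
save_model <- function(fit, path) {
  saveRDS(fit, path)
  invisible(path)
}

#' Load a model checkpoint written by [save_model()]
#' @param path Checkpoint path.
#' @return The `msmda_fit`.
#' @export
load_model <- function(path) {
  fit <- readRDS(path)
  if (!inherits(fit, "msmda_fit")) {
    stopf("'%s' is not an msmda checkpoint", path, class = "msmda_io_error")
  }
  fit
}
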