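#' Method specification for the study harnesses
#'
#' Two families share one backbone: `"msmda"` keeps every source as its own
#' adaptation branch; `"single_branch"` concatenates all sources into one big
#' source domain first (the source-combine strategy) and trains a one-branch
#' model. The single-branch family with the different alignment losses
#' recovers the classic baselines on this backbone: multi-kernel MMD (DAN
#' style), single-kernel MMD (DDC style), correlation alignment (deep CORAL
#' style), or no alignment (source-only).
#'
#' @param name `"msmda"` or `"single_branch"`.
#' @param alignment `"mmd_multi"`, `"mmd_single"`, `"coral"` or `"none"`.
#' @param use_disc Use the discrepancy regulariser (forced `FALSE` for
#'   single-branch, where it is identically zero anyway).
#' @return An object of class `method_spec`.
#' @export
method_spec <- function(name = c("msmda", "single_branch"),
                        alignment = c("mmd_multi", "mmd_single", "coral", "none"),
                        use_disc = NULL) {
  name <- match.arg(name)
  alignment <- match.arg(alignment)
  if (is.null(use_disc)) use_disc <- name == "msmda"
  if (name == "single_branch") use_disc <- FALSE
  structure(list(name = name, alignment = alignment,
                 use_disc = isTRUE(use_disc),
                 combine_sources = name == "single_branch"),
            class = "method_spec")
}

method_label <- function(method) {
  paste0(method$name, "/", method$alignment,
         if (method$use_disc) "" else "/no_disc")
}

# Translate a method_spec into the train_config alignment fields.
apply_method <- function(tcfg, method) {
  switch(method$alignment,
    mmd_multi = {
      tcfg$alignment <- "mmd"
      tcfg$kernel <- kernel_spec("rbf_multi", n_kernels = tcfg$kernel$n_kernels,
                                 ladder_base = tcfg$kernel$ladder_base,
                                 anchor = tcfg$kernel$anchor)
    },
    mmd_single = {
      tcfg$alignment <- "mmd"
      tcfg$kernel <- kernel_spec("rbf_single", anchor = tcfg$kernel$anchor)
    },
    coral = tcfg$alignment <- "coral",
    none = {
      tcfg$alignment <- "none"
      tcfg$weights$alpha_scale <- 0
    }
  )
  if (!method$use_disc) tcfg$weights$beta_weight <- 0
  tcfg
}

#' Collapse a task's sources into one combined source domain
#'
#' Row-binds all source feature matrices and labels into a single domain —
#' the source-combine strategy the multi-branch design argues against.
#'
#' @param task A [multisource_task()].
#' @return A [multisource_task()] with one source.
#' @export
combine_sources <- function(task) {
  X <- do.call(rbind, lapply(task$sources, function(d) d$features))
  y <- unlist(lapply(task$sources, function(d) d$labels), use.names = FALSE)
  multisource_task(
    list(domain_dataset(X, labels = y, domain_id = "combined")),
    task$target, task$n_classes,
    task_id = paste0(task$task_id, "/combined")
  )
}

#' Train one method on one task and record the outcome
#'
#' The workhorse behind every study harness: applies the method's alignment
#' and discrepancy settings to the training configuration, combines sources
#' when the method asks for it, trains, and evaluates target accuracy.
#'
#' @param task A [multisource_task()].
#' @param method A [method_spec()].
#' @param mcfg A [model_config()] template (branch count and class count are
#'   filled from the task), or `NULL` for defaults.
#' @param tcfg A [train_config()].
#' @return One-row tibble result record.
#' @export
run_method <- function(task, method, mcfg = NULL, tcfg = train_config()) {
  tcfg <- apply_method(tcfg, method)
  run_task_cfg(task, method, mcfg, tcfg)
}

run_task_cfg <- function(task, method, mcfg, tcfg) {
  if (method$combine_sources) task <- combine_sources(task)
  if (!is.null(mcfg)) {
    mcfg$n_sources <- length(task$sources)
    mcfg$n_classes <- task$n_classes
    mcfg$input_dim <- ncol(task$target$features)
    mcfg <- do.call(model_config, unclass(mcfg))
  }
  fit <- train_msmda(task, mcfg, tcfg)
  acc <- evaluate_accuracy(fit, task$target)
  h <- fit$history
  label <- method_label(method)
  combines <- method$combine_sources
  tibble::tibble(
    task_id = task$task_id,
    method = label,
    combine_sources = combines,
    n_sources = length(task$sources),
    seed = tcfg$seed,
    accuracy = acc,
    final_loss_total = h$loss_total[nrow(h)],
    final_loss_cls = h$loss_cls[nrow(h)],
    final_loss_mmd = h$loss_mmd[nrow(h)],
    final_loss_disc = h$loss_disc[nrow(h)]
  )
}

#' Population standard deviation
#' @param x Numeric vector.
#' @return `sqrt(mean((x - mean(x))^2))`.
#' @export
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Aggregate per-task records into mean and spread
#'
#' @param records Tibble of result records with an `accuracy` column.
#' @param by Grouping columns (default `"method"`).
#' @return Tibble with `mean_accuracy`, `sd_accuracy` (population sd, the
#'   "+/-" convention of the result tables) and `n_runs` per group.
#' @export
aggregate_results <- function(records, by = "method") {
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      mean_accuracy = mean(.data$accuracy),
      sd_accuracy = pop_sd(.data$accuracy),
      n_runs = dplyr::n(),
      .groups = "drop"
    )
}

#' Run a transfer protocol across a collection
#'
#' Builds the protocol's tasks from the collection, optionally normalizes
#' each task, trains the requested method on every (task, seed) pair, and
#' aggregates accuracy as mean and population sd across tasks (and seeds).
#'
#' @param coll A [domain_collection()].
#' @param protocol `"cross_session"` or `"cross_subject"`.
#' @param method A [method_spec()].
#' @param mcfg A [model_config()] template (dims; branch count and class
#'   count are filled per task), or `NULL` for defaults.
#' @param tcfg A [train_config()] template; its `seed` is replaced per run.
#' @param seeds Integer vector of training seeds (default the template's).
#' @param normalization Normalization type applied per task via
#'   [normalize_task()] (default `"electrode_wise"`).
#' @param norm_order Source normalization order (default
#'   `"normalize_then_concat"`).
#' @return List with `records` (one row per task x seed) and `summary`
#'   (via [aggregate_results()]).
#' @export
run_protocol <- function(coll, protocol = c("cross_session", "cross_subject"),
                         method = method_spec("msmda"), mcfg = NULL,
                         tcfg = train_config(), seeds = NULL,
                         normalization = "electrode_wise",
                         norm_order = "normalize_then_concat") {
  protocol <- match.arg(protocol)
  if (is.null(seeds)) seeds <- tcfg$seed
  tasks <- build_tasks(coll, protocol)
  records <- purrr::map_dfr(seeds, function(sd) {
    purrr::map_dfr(tasks, function(task) {
      if (normalization != "none") {
        task <- normalize_task(task, normalization, norm_order)
      }
      tcfg$seed <- as.integer(sd)
      run_method(task, method, mcfg, tcfg)
    })
  })
  list(records = records, summary = aggregate_results(records))
}

#' Train a single-branch source-combine baseline on one task
#'
#' @param task A [multisource_task()].
#' @param alignment `"mmd_multi"`, `"mmd_single"`, `"coral"` or `"none"`.
#' @param mcfg,tcfg Configuration templates (see [run_protocol()]).
#' @return One-row result record tibble (with `combine_sources = TRUE`).
#' @export
run_single_branch_baseline <- function(task, alignment = "mmd_multi",
                                       mcfg = NULL, tcfg = train_config()) {
  run_method(task, method_spec("single_branch", alignment), mcfg, tcfg)
}

#' Leave-one-loss-out ablation of the full model
#'
#' Trains four variants on the same task with shared seeds: the full model,
#' the model without the MMD term (alpha forced 0), without the discrepancy
#' term (beta forced 0), and without both. Differences between rows reflect
#' the removed terms, not sampling.
#'
#' @param task A [multisource_task()].
#' @param mcfg,tcfg Configuration templates.
#' @param seeds Integer vector of seeds; each variant runs once per seed.
#' @return Tibble of `4 * length(seeds)` records; `variant` is one of
#'   `"full"`, `"w/o MMD"`, `"w/o disc"`, `"w/o both"`.
#' @export
run_ablation <- function(task, mcfg = NULL, tcfg = train_config(),
                         seeds = tcfg$seed) {
  variants <- list(
    "full" = c(alpha = 1, beta = 1),
    "w/o MMD" = c(alpha = 0, beta = 1),
    "w/o disc" = c(alpha = 1, beta = 0),
    "w/o both" = c(alpha = 0, beta = 0)
  )
  purrr::map_dfr(seeds, function(sd) {
    purrr::map_dfr(names(variants), function(v) {
      tv <- tcfg
      tv$seed <- as.integer(sd)
      if (variants[[v]][["alpha"]] == 0) {
        tv$weights$alpha_scale <- 0
        tv$alignment <- "none"
      }
      if (variants[[v]][["beta"]] == 0) tv$weights$beta_weight <- 0
      method <- method_spec("msmda",
                            alignment = if (variants[[v]][["alpha"]] == 0) "none" else "mmd_multi",
                            use_disc = variants[[v]][["beta"]] == 1)
      rec <- run_task_cfg(task, method, mcfg, tv)
      rec$variant <- v
      rec
    })
  })
}

#' Accuracy as a function of the number of source branches
#'
#' For `k = 1 .. max_sources`, trains on the task restricted to its first
#' `k` sources, with shared seeds, tracing how accuracy grows with the
#' number of adaptation branches.
#'
#' @param task A [multisource_task()] with at least `max_sources` sources,
#'   or a [domain_collection()] (then `protocol` selects the task family and
#'   the sweep runs on its first task).
#' @param max_sources Largest branch count.
#' @param ks Optional integer vector of branch counts to run (default
#'   `1:max_sources`); must be `<= max_sources`.
#' @param mcfg,tcfg Configuration templates.
#' @param seeds Integer vector of seeds.
#' @param protocol Used only when `task` is a collection.
#' @return Tibble with one record per (k, seed), column `k`.
#' @export
run_source_sweep <- function(task, max_sources = NULL,
                             ks = NULL, mcfg = NULL,
                             tcfg = train_config(), seeds = tcfg$seed,
                             protocol = "cross_subject") {
  if (inherits(task, "domain_collection")) {
    task <- build_tasks(task, protocol)[[1L]]
  }
  if (is.null(max_sources)) max_sources <- length(task$sources)
  if (is.null(ks)) ks <- seq_len(max_sources)
  if (max_sources > length(task$sources)) {
    stopf("task has %d sources, requested %d", length(task$sources),
          max_sources, class = "msmda_config_error")
  }
  purrr::map_dfr(seeds, function(sd) {
    purrr::map_dfr(ks, function(k) {
      sub <- multisource_task(task$sources[seq_len(k)], task$target,
                              task$n_classes,
                              task_id = sprintf("%s/k%d", task$task_id, k))
      tv <- tcfg
      tv$seed <- as.integer(sd)
      rec <- run_method(sub, method_spec("msmda"), mcfg, tv)
      rec$k <- k
      rec
    })
  })
}

#' Normalization-study grid
#'
#' Crosses the four normalization types with the two application orders for
#' each requested method, with shared seeds. For multi-branch msmda the
#' source pool is never concatenated, so the two orders provably coincide
#' (each source is normalized with its own statistics either way); those
#' cells are annotated `order_invariant = TRUE` and computed once, mirroring
#' the order-invariant cells of the published grid.
#'
#' @param task A [multisource_task()] (raw, un-normalized features), or a
#'   [domain_collection()] (then `protocol` selects the first task).
#' @param methods List of [method_spec()] objects.
#' @param types Normalization types (default the four studied).
#' @param mcfg,tcfg Configuration templates.
#' @param seeds Integer vector of seeds.
#' @param protocol Used only when `task` is a collection.
#' @return Tibble with one row per (type, order, method, seed); columns
#'   `normalization`, `norm_order`, `order_invariant`. Order-invariant cells
#'   (any type for non-combining methods, and type `"none"` for everyone)
#'   are computed once and reported under both orders.
#' @export
run_normalization_grid <- function(task,
                                   methods = list(method_spec("msmda"),
                                                  method_spec("single_branch")),
                                   types = c("none", "electrode_wise",
                                             "sample_wise", "global_wise"),
                                   mcfg = NULL, tcfg = train_config(),
                                   seeds = tcfg$seed,
                                   protocol = "cross_subject") {
  if (inherits(task, "domain_collection")) {
    task <- build_tasks(task, protocol)[[1L]]
  }
  orders <- c("normalize_then_concat", "concat_then_normalize")
  purrr::map_dfr(seeds, function(sd) {
    purrr::map_dfr(methods, function(method) {
      purrr::map_dfr(types, function(tp) {
        # per-source normalization makes order moot for non-combining
        # methods; "none" is order-free for everyone
        invariant <- !method$combine_sources || tp == "none"
        purrr::map_dfr(orders, function(od) {
          if (invariant && od == "concat_then_normalize") {
            return(NULL)  # duplicated from the computed order below
          }
          tn <- if (tp == "none") task else normalize_task(task, tp, od)
          tv <- tcfg
          tv$seed <- as.integer(sd)
          rec <- run_method(tn, method, mcfg, tv)
          rec$normalization <- tp
          rec$norm_order <- od
          rec$order_invariant <- invariant
          if (invariant) {
            rec2 <- rec
            rec2$norm_order <- "concat_then_normalize"
            rec <- dplyr::bind_rows(rec, rec2)
          }
          rec
        })
      })
    })
  })
}
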