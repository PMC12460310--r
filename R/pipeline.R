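# End-to-end traceability pipeline: simulate (or load) spectra -> per-sample
# synchronous correlation images -> 50/25/15 split -> 12-layer residual CNN
# vs. the PLS-DA baseline -> metrics report and run manifest.

#' Configuration of a traceability run
#'
#' @param generator a [generator_config()] describing the synthetic study, or
#'   `NULL` when `spectra` are supplied to [run_traceability()] directly.
#' @param split_sizes `(train, test, external)` sample counts; the study
#'   design is 50/25/15 over 90 bulbs.
#' @param split_seed seed of the random split.
#' @param image_size side of the square correlation images fed to the CNN.
#' @param resnet a [resnet_config()]; its `input_size` is derived from
#'   `image_size` when `NULL`.
#' @param n_lv latent variables of the PLS-DA baseline.
#' @param out_dir directory for artifacts (CSV tables, manifest), or `NULL`
#'   to keep the report in memory only.
#' @return A `traceability_config` list.
#' @export
traceability_config <- function(generator = generator_config(seed = 1L),
                                split_sizes = c(50L, 25L, 15L),
                                split_seed = 1L,
                                image_size = 224L,
                                resnet = NULL,
                                n_lv = 2L,
                                out_dir = NULL) {
  if (is.null(resnet) && !is.null(generator)) {
    resnet <- resnet_config(n_classes = generator$n_classes,
                            input_size = c(image_size, image_size, 1L),
                            seed = generator$seed %||% 1L)
  }
  structure(list(generator = generator, split_sizes = as.integer(split_sizes),
                 split_seed = split_seed, image_size = as.integer(image_size),
                 resnet = resnet, n_lv = as.integer(n_lv),
                 out_dir = out_dir),
            class = "traceability_config")
}

#' Run the full traceability analysis
#'
#' Stages: (1) generate or accept a labeled spectra set; (2) random
#' train/test/external split; (3) per-sample rank-1 synchronous correlation
#' images against the training-set mean spectrum, rendered under the
#' training-set global intensity scale; (4) train the 12-layer residual CNN;
#' (5) fit the PLS-DA baseline on the raw spectra; (6) evaluate both on the
#' test and external sets and assemble a comparison table. Any stage failure
#' aborts with a stage-named error.
#'
#' @param config a [traceability_config()].
#' @param spectra optional pre-made [spectra_set()] (overrides the
#'   generator).
#' @param verbose print per-epoch training progress.
#' @return A `traceability_report`: the split, training curves, confusion
#'   matrices, a `comparison` data frame (accuracy and macro
#'   precision/sensitivity/specificity for both models on both held-out
#'   sets), and the run manifest.
#' @export
run_traceability <- function(config = traceability_config(),
                             spectra = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "traceability_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  set <- stage("simulate", {
    if (is.null(spectra)) generate_spectra_set(config$generator) else spectra
  })
  if (is.null(set$labels)) stopf("stage 'simulate' failed: spectra must be labeled")
  n <- n_spectra(set)

  split <- stage("split", split_dataset(n, config$split_sizes,
                                        seed = config$split_seed))

  imgs <- stage("cos3d", {
    train_mean <- colMeans(set$reflectance[split$train, , drop = FALSE])
    train_imgs <- cos_images(subset_spectra(set, split$train),
                             reference = train_mean,
                             size = config$image_size)
    test_imgs <- cos_images(subset_spectra(set, split$test),
                            reference = train_mean,
                            size = config$image_size,
                            limits = train_imgs$limits)
    ext_imgs <- cos_images(subset_spectra(set, split$external),
                           reference = train_mean,
                           size = config$image_size,
                           limits = train_imgs$limits)
    list(train = train_imgs, test = test_imgs, external = ext_imgs,
         reference = train_mean, limits = train_imgs$limits)
  })

  lab <- set$labels
  cnn <- stage("train", {
    net <- build_resnet12(config$resnet)
    train_resnet(net, imgs$train$images, lab[split$train],
                 test_images = imgs$test$images,
                 test_labels = lab[split$test],
                 verbose = verbose)
  })

  cnn_eval <- stage("evaluate", {
    list(test = evaluate_resnet(cnn$net, imgs$test$images, lab[split$test]),
         external = evaluate_resnet(cnn$net, imgs$external$images,
                                    lab[split$external]))
  })

  pls <- stage("chemo", {
    model <- plsda_fit(set$reflectance[split$train, , drop = FALSE],
                       lab[split$train], n_lv = config$n_lv)
    conf_of <- function(idx) {
      pr <- plsda_predict(model, set$reflectance[idx, , drop = FALSE])
      conf <- table(truth = factor(lab[idx], levels = levels(lab)),
                    predicted = pr$class)
      matrix(as.integer(conf), nrow(conf), ncol(conf),
             dimnames = dimnames(conf))
    }
    list(model = model, test = conf_of(split$test),
         external = conf_of(split$external))
  })

  comparison <- stage("report", {
    row_for <- function(model, setname, conf) {
      m <- confusion_metrics(conf)
      data.frame(model = model, set = setname,
                 accuracy = m$accuracy,
                 macro_precision = m$macro["precision"],
                 macro_sensitivity = m$macro["sensitivity"],
                 macro_specificity = m$macro["specificity"],
                 row.names = NULL)
    }
    rbind(row_for("resnet12", "test", cnn_eval$test),
          row_for("resnet12", "external", cnn_eval$external),
          row_for("plsda", "test", pls$test),
          row_for("plsda", "external", pls$external))
  })

  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    n_samples = n,
    split_sizes = as.integer(config$split_sizes),
    split_seed = config$split_seed,
    image_size = config$image_size,
    intensity_limits = as.numeric(imgs$limits),
    resnet = config$resnet[c("n_classes", "filters", "learning_rate",
                             "weight_decay", "momentum", "epochs",
                             "batch_size", "seed")],
    plsda_n_lv = config$n_lv,
    generator_seed = if (!is.null(config$generator)) config$generator$seed,
    epochs_run = cnn$epochs_run,
    best_test_epoch = cnn$best_epoch)

  report <- structure(list(
    split = split,
    curves = cnn$curves,
    best_test_acc = cnn$best_test_acc,
    best_epoch = cnn$best_epoch,
    confusion = list(resnet_test = cnn_eval$test,
                     resnet_external = cnn_eval$external,
                     plsda_test = pls$test,
                     plsda_external = pls$external),
    comparison = comparison,
    manifest = manifest,
    net = cnn$net,
    pls_model = pls$model,
    reference_spectrum = imgs$reference),
    class = "traceability_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.traceability_report <- function(x, ...) {
  cat("<traceability_report>\n")
  cat(sprintf("  split: %d/%d/%d, epochs run: %d (best test acc %.3f at epoch %s)\n",
              length(x$split$train), length(x$split$test),
              length(x$split$external), nrow(x$curves),
              x$best_test_acc,
              if (is.na(x$best_epoch)) "-" else x$best_epoch))
  print(x$comparison, digits = 4)
  invisible(x)
}

#' Write a traceability report's tables and manifest to a directory
#'
#' Emits `comparison.csv`, `curves.csv`, one CSV per confusion matrix, and
#' `manifest.yaml`. Reruns with an identical configuration reproduce
#' byte-identical CSV tables.
#'
#' @param report a `traceability_report`.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "traceability_report"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$comparison,
                   file.path(out_dir, "comparison.csv"), row.names = FALSE)
  utils::write.csv(report$curves, file.path(out_dir, "curves.csv"),
                   row.names = FALSE)
  for (nm in names(report$confusion)) {
    utils::write.csv(report$confusion[[nm]],
                     file.path(out_dir, paste0("confusion_", nm, ".csv")))
  }
  yaml::write_yaml(report$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
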