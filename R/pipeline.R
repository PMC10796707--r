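#' Default run configuration
#'
#' One declarative document holding every tunable parameter of the two
#' workflows, with the package defaults filled in. Configurations read
#' from YAML ([readRunConfig()]) are validated against this template:
#' unknown keys are rejected.
#'
#' @return A nested named list.
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1L,
    input = list(counts = NULL, coords = NULL, format = "csv_pair",
                 platform = "generic"),
    image = list(mode = "auto", sigma = 1.0, flip_y = FALSE),
    pattern_index = list(kernel_size = NULL, del_rate = 0.01,
                         psi = "minmax"),
    tests = list(alpha = 0.05, n_perms = 999L, weights = "grid_queen",
                 k = 6L, row_standardize = FALSE,
                 assumption = "randomization"),
    embedding = list(k = NULL, gamma = 2 / 3, t = 2L, n_pcs = 50L,
                     n_svgs = 3000L, min_spots = 10L, aggregate = "self",
                     slope = 0.2),
    clustering = list(n_clusters = NULL, resolution = 1, init = "mclust",
                      nu = 0.5, lr = 1e-3, max_epochs = 500L, tol = 1e-3,
                      p_update_every = 3L, postprocess = TRUE,
                      n_passes = 1L)
  )
}

# Merge user values over defaults, rejecting keys the template lacks.
mergeConfig <- function(defaults, user, path = "") {
  extra <- setdiff(names(user), names(defaults))
  if (length(extra))
    stop("unknown configuration key(s): ",
         paste0(path, extra, collapse = ", "))
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- mergeConfig(defaults[[nm]], as.list(user[[nm]]),
                                    paste0(path, nm, "."))
    } else defaults[nm] <- user[nm]
  }
  defaults
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with any subset of the [defaultRunConfig()]
#'   keys; missing keys take their defaults, unknown keys are an error.
#' @return The merged configuration list.
#' @export
readRunConfig <- function(path) {
  mergeConfig(defaultRunConfig(), yaml::read_yaml(path))
}

.loadInput <- function(config) {
  inp <- config$input
  if (is.null(inp$counts))
    stop("[io] no input counts path configured")
  if (!file.exists(inp$counts))
    stop("[io] input path does not exist: ", inp$counts)
  readSpotTable(inp$counts, format = inp$format, coordPath = inp$coords,
                platform = inp$platform)
}

.writeManifest <- function(manifest, outDir) {
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
}

#' Spatially-variable-gene workflow
#'
#' Reads (or takes) a spot table, scores every gene with the pattern
#' index, runs the parametric and permutation autocorrelation tests, and
#' calls SVGs. When `outDir` is given, writes `svg_results.csv` and a
#' `manifest.json` recording every parameter, the seed, the package
#' version and the dropped/called gene counts, so a run can be replayed
#' bit-identically.
#'
#' @param config a [defaultRunConfig()]-shaped list.
#' @param table optional [SpotTable-class]; read from `config$input`
#'   when `NULL`.
#' @param outDir optional output directory (created if needed).
#' @return `list(records, manifest)`; `records` is the [selectSVGs()]
#'   table.
#' @export
runSVGWorkflow <- function(config = defaultRunConfig(), table = NULL,
                           outDir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  if (is.null(table)) table <- .loadInput(config)
  mapping <- gridMapping(table, mode = config$image$mode,
                         flipY = config$image$flip_y)
  pi <- withCallingHandlers(
    scoreGenePatterns(table, mapping, sigma = config$image$sigma,
                      kernelSize = config$pattern_index$kernel_size,
                      delRate = config$pattern_index$del_rate,
                      psi = config$pattern_index$psi),
    error = function(e) stop("[pattern_index] ", conditionMessage(e)))
  t1 <- proc.time()[["elapsed"]]
  tests <- withCallingHandlers(
    runAutocorrTests(table, mapping, rule = config$tests$weights,
                     k = config$tests$k,
                     rowStandardize = config$tests$row_standardize,
                     assumption = config$tests$assumption,
                     nPerms = config$tests$n_perms, seed = config$seed),
    error = function(e) stop("[autocorr_tests] ", conditionMessage(e)))
  records <- selectSVGs(pi, tests, alpha = config$tests$alpha)
  t2 <- proc.time()[["elapsed"]]
  manifest <- list(
    workflow = "svg",
    package_version = as.character(utils::packageVersion("SpotPattern")),
    seed = config$seed,
    parameters = config[c("image", "pattern_index", "tests")],
    grid = list(mode = mapping@mode, H = mapping@H, W = mapping@W,
                n_valid_pixels = sum(mapping@validMask)),
    n_genes = nrow(table), n_spots = ncol(table),
    n_dropped = sum(records$dropped), n_svgs = sum(records$is_svg),
    timings_sec = list(pattern_index = round(t1 - t0, 2),
                       tests = round(t2 - t1, 2)))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(as.data.frame(records),
                       file.path(outDir, "svg_results.csv"))
    .writeManifest(manifest, outDir)
  }
  list(records = records, manifest = manifest)
}

#' Spatial-domain workflow
#'
#' Pre-processes the expression (detection filter, per-spot total
#' normalization, log transform, top-SVG selection when records are
#' supplied), builds the kNN spot graph, Laplacian-smooths the top
#' principal components, trains the attention embedding with
#' self-supervised clustering, and optionally smooths the labels
#' spatially. When `outDir` is given, writes `domains.csv`,
#' `embedding.csv`, `loss_history.csv` and a full `manifest.json`; when
#' `trueLabels` is supplied the achieved ARI and NMI are recorded in the
#' manifest.
#'
#' @inheritParams runSVGWorkflow
#' @param piRecords optional [scoreGenePatterns()] table for top-SVG
#'   feature selection.
#' @param trueLabels optional ground-truth labels for evaluation.
#' @return `list(labels, state, embedding, manifest)`.
#' @export
runDomainWorkflow <- function(config = defaultRunConfig(), table = NULL,
                              piRecords = NULL, trueLabels = NULL,
                              outDir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  if (is.null(table)) table <- .loadInput(config)
  emb <- config$embedding
  clu <- config$clustering
  x <- withCallingHandlers(
    preprocessExpression(table, piRecords, nSVGs = emb$n_svgs,
                         minSpots = emb$min_spots),
    error = function(e) stop("[embedding] ", conditionMessage(e)))
  keptSpots <- rownames(x)
  coords <- spotCoords(table)[keptSpots, , drop = FALSE]
  kGraph <- emb$k %||% .platformGraphK(spotPlatform(table))
  graph <- buildGraph(coords, k = kGraph)
  xp <- pcaReduce(x, nComponents = emb$n_pcs)
  xt <- laplacianSmooth(xp, graph, gamma = emb$gamma, t = emb$t)
  model <- attentionModel(dIn = ncol(xt), dOut = ncol(xt),
                          slope = emb$slope, aggregate = emb$aggregate,
                          seed = config$seed)
  h0 <- attentionForward(xt, graph, model)$h
  init <- withCallingHandlers(
    initCenters(h0, method = clu$init, k = clu$n_clusters,
                resolution = clu$resolution, seed = config$seed),
    error = function(e) stop("[cluster] ", conditionMessage(e)))
  state <- trainCluster(xt, graph, model, init$centers, nu = clu$nu,
                        lr = clu$lr, maxEpochs = clu$max_epochs,
                        tol = clu$tol, pUpdateEvery = clu$p_update_every)
  labels <- state@labels
  if (isTRUE(clu$postprocess))
    labels <- postprocessLabels(labels, coords, k = kGraph,
                                nPasses = clu$n_passes)
  t1 <- proc.time()[["elapsed"]]
  manifest <- list(
    workflow = "domain",
    package_version = as.character(utils::packageVersion("SpotPattern")),
    seed = config$seed,
    parameters = config[c("embedding", "clustering")],
    graph_k = kGraph, n_spots = length(labels), n_features = ncol(x),
    n_clusters = length(unique(labels)),
    n_epochs = length(state@lossHistory),
    final_loss = utils::tail(state@lossHistory, 1),
    timings_sec = list(total = round(t1 - t0, 2)))
  if (!is.null(trueLabels)) {
    keep <- match(keptSpots, colnames(table))
    manifest$ari <- ariScore(labels, trueLabels[keep])
    manifest$nmi <- nmiScore(labels, trueLabels[keep])
  }
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(data.frame(spot_id = keptSpots, domain = labels),
                       file.path(outDir, "domains.csv"))
    embOut <- data.frame(spot_id = keptSpots, state@embedding)
    names(embOut)[-1] <- paste0("dim", seq_len(ncol(state@embedding)))
    data.table::fwrite(embOut, file.path(outDir, "embedding.csv"))
    data.table::fwrite(data.frame(epoch = seq_along(state@lossHistory),
                                  loss = state@lossHistory),
                       file.path(outDir, "loss_history.csv"))
    .writeManifest(manifest, outDir)
  }
  list(labels = labels, state = state, embedding = state@embedding,
       manifest = manifest)
}
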