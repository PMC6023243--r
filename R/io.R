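#' Read a network model from a JSON file
#'
#' The schema is an object with `states` (array of `{id, label,
#' measurement}` with ids exactly `1..n` in order), `edges` (array of
#' `{from, to, rate}`) and `n_walkers`. The measurement is required; there
#' is no default. Parsing is strict: schema violations name the offending
#' field.
#'
#' @param path file path.
#' @return a validated [MarkovNetworkModel-class].
#' @seealso [writeMarkovModel()] for the inverse; models round-trip
#'   bit-identically (canonical key order, 17 significant digits).
#' @export
readMarkovModel <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (field in c("states", "edges", "n_walkers"))
    if (is.null(x[[field]])) stop("model file missing field '", field, "'")
  st <- x$states
  for (field in c("id", "label", "measurement"))
    if (is.null(st[[field]]))
      stop("model file missing field 'states.", field, "'")
  if (!identical(as.integer(st$id), seq_len(nrow(st))))
    stop("field 'states.id' must be contiguous 1..n in order")
  ed <- x$edges
  for (field in c("from", "to", "rate"))
    if (is.null(ed[[field]]))
      stop("model file missing field 'edges.", field, "'")
  buildModel(states = data.frame(id = st$id, label = st$label),
             edges = ed[, c("from", "to", "rate")],
             measurement = as.numeric(st$measurement),
             nWalkers = x$n_walkers)
}

#' Write a network model to JSON
#'
#' Canonical key order and 17 significant digits, so that
#' write-then-read reproduces the model exactly.
#'
#' @param model a [MarkovNetworkModel-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeMarkovModel <- function(model, path) {
  obj <- list(
    states = data.frame(id = seq_len(model@nStates),
                        label = model@stateLabels,
                        measurement = model@measurement),
    edges = model@edges[, c("from", "to", "rate")],
    n_walkers = model@nWalkers)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

# commented metadata header written at the top of every TSV report
.tsvHeader <- function(con, what, seed = NA) {
  cat(sprintf("# stochShield %s | %s | generated %s | seed %s\n",
              as.character(utils::packageVersion("stochShield")), what,
              format(Sys.time(), "%Y-%m-%d"),
              if (is.na(seed)) "n/a" else seed),
      file = con)
}

#' Write a per-edge importance report as TSV
#'
#' One row per directed edge with its rate, per-walker flux, importance
#' \eqn{R_k}, relative importance, state pair and pair-aggregated relative
#' importance, preceded by a commented metadata line.
#'
#' @param model a reversible [MarkovNetworkModel-class].
#' @param path output path.
#' @param what short description stored in the header.
#' @return the report data.frame, invisibly.
#' @export
writeImportanceReport <- function(model, path, what = "edge importance") {
  ei <- edgeImportance(model)
  ss <- stationarySummary(model)
  e <- model@edges
  rep <- data.frame(
    edge_index = e$k, source = e$from, target = e$to, rate = e$rate,
    flux_per_walker = ss@perWalkerFlux, R_k = ei@perEdge,
    relative = ei@relative, pair = ei@pairOfEdge,
    pair_relative = as.numeric(ei@pairRelative[ei@pairOfEdge]))
  con <- file(path, "w")
  on.exit(close(con))
  .tsvHeader(con, what)
  utils::write.table(format(rep, digits = 17), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(rep)
}

#' Write a spectral density table as TSV
#'
#' @param table result of [psd()].
#' @param path output path.
#' @param subsets optional named list of edge index vectors whose summed
#'   densities are appended as extra columns.
#' @return the data.frame written, invisibly.
#' @export
writePsdTable <- function(table, path, subsets = list()) {
  df <- data.frame(omega = table$omega, t(table$perEdge),
                   total = table$total)
  names(df) <- c("omega", paste0("edge", seq_len(nrow(table$perEdge))),
                 "total")
  for (nm in names(subsets))
    df[[nm]] <- colSums(table$perEdge[subsets[[nm]], , drop = FALSE])
  con <- file(path, "w")
  on.exit(close(con))
  .tsvHeader(con, "power spectral density (two-sided, angular frequency)")
  utils::write.table(format(df, digits = 17), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Write Langevin trajectories as TSV
#'
#' Time column, one column per state for the full process, then the
#' observable of each shielded approximation; the header records seed,
#' dt and the retained sets.
#'
#' @param trajectories a [TrajectorySet-class].
#' @param path output path.
#' @return the data.frame written, invisibly.
#' @export
writeTrajectories <- function(trajectories, path) {
  ts <- trajectories
  M <- measurement(ts@model)
  df <- data.frame(time = ts@times, ts@full)
  names(df) <- c("time", paste0("full.", stateLabels(ts@model)))
  for (nm in names(ts@approximations))
    df[[paste0("obs.", nm)]] <- as.numeric(ts@approximations[[nm]] %*% M)
  con <- file(path, "w")
  on.exit(close(con))
  .tsvHeader(con, sprintf("Langevin trajectories | dt=%g | retained: %s",
                          ts@dt,
                          paste(vapply(ts@retainedSets, paste,
                                       character(1), collapse = ","),
                                collapse = " | ")),
             seed = ts@seed)
  utils::write.table(format(df, digits = 10), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Write a jump trajectory as TSV
#'
#' Columns: event_time, edge_index, then one column per state.
#'
#' @param trajectory a [JumpTrajectory-class].
#' @param model the simulated [MarkovNetworkModel-class] (for labels).
#' @param path output path.
#' @return the data.frame written, invisibly.
#' @export
writeJumpTrajectory <- function(trajectory, model, path) {
  df <- data.frame(event_time = trajectory@eventTimes,
                   edge_index = trajectory@edgeIndices,
                   trajectory@statesAfterEvent)
  names(df) <- c("event_time", "edge_index", stateLabels(model))
  con <- file(path, "w")
  on.exit(close(con))
  .tsvHeader(con, "SSA jump trajectory", seed = trajectory@seed)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Write an ensemble sample table as TSV
#'
#' One row per sampled rate quadruple with its diagnostics; the header
#' records w, n, seed and the log base.
#'
#' @param ensemble an [EnsembleResult-class].
#' @param path output path.
#' @return the data.frame written, invisibly.
#' @export
writeEnsemble <- function(ensemble, path) {
  con <- file(path, "w")
  on.exit(close(con))
  .tsvHeader(con, sprintf("lognormal ensemble | w=%g | n=%d | log base %s",
                          ensemble@w, ensemble@nSamples, ensemble@logBase),
             seed = ensemble@seed)
  utils::write.table(format(ensemble@samples, digits = 17), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(ensemble@samples)
}
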