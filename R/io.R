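# I/O: trace CSV with unit-annotated headers, morphology YAML round trip,
# SWC export, experiment configuration files, and metric JSON.

.col_unit <- function(name) {
  if (name == "time_ms") return("ms")
  pre <- sub("_.*$", "", name)
  switch(pre,
         v = "mV",
         ina = "pA", ik = "pA", ica = "pA",
         i = "pA", g = "nS", "")
}

#' Write a trace set to CSV
#'
#' Columns are written in their (deterministic) order with the unit appended
#' to every header (`v_soma.mV`, `ica_bouton_1.pA`, ...); values round-trip
#' through [read_traces()] to 12 significant digits.
#'
#' @param traces an `mf_traces` data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  df <- as.data.frame(traces)
  hdr <- vapply(names(df), function(nm) {
    u <- .col_unit(nm)
    if (nzchar(u) && nm != "time_ms") paste0(nm, ".", u) else nm
  }, character(1))
  out <- df
  names(out) <- hdr
  for (j in seq_along(out)) out[[j]] <- signif(out[[j]], 12)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trace CSV written by [write_traces()]
#' @param path file path.
#' @return data.frame with the unit suffixes stripped from the headers.
#' @export
read_traces <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  names(df) <- sub("\\.[^.]*$", "", names(df))
  class(df) <- c("mf_traces", "data.frame")
  df
}

#' Serialize a morphology to YAML
#' @param m an `mf_morphology`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
morphology_to_yaml <- function(m, path) {
  secs <- lapply(seq_len(nrow(m$sections)), function(i) {
    s <- as.list(m$sections[i, ])
    if (is.na(s$parent_id)) s$parent_id <- NULL
    if (is.na(s$parent_pos)) s$parent_pos <- NULL
    s
  })
  yaml::write_yaml(list(sections = secs, passive = m$passive), path)
  invisible(path)
}

#' Read a morphology from YAML
#' @param path file written by [morphology_to_yaml()].
#' @return an `mf_morphology`.
#' @export
morphology_from_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  secs <- do.call(rbind, lapply(x$sections, function(s) {
    data.frame(id = s$id, kind = s$kind, length = s$length,
               diam_prox = s$diam_prox, diam_dist = s$diam_dist,
               parent_id = if (is.null(s$parent_id)) NA_character_
                           else s$parent_id,
               parent_pos = if (is.null(s$parent_pos)) NA_real_
                            else s$parent_pos,
               stringsAsFactors = FALSE)
  }))
  m <- structure(list(sections = secs, passive = x$passive),
                 class = "mf_morphology")
  validate_morphology(m)
  m
}

# SWC type codes used on export: 1 soma, 2 axon (incl. boutons, filopodia,
# collaterals), 3 dendrite.
.swc_type <- function(kind) {
  ifelse(kind == "soma", 1L,
         ifelse(startsWith(kind, "dendrite"), 3L, 2L))
}

#' Export a morphology to SWC
#'
#' Standard 7-column SWC with two sample points per section (proximal,
#' distal); sections are laid out along abstract coordinates (x = path
#' distance from the root origin, y = a branch offset), which preserves
#' topology and radii for viewers but is not an anatomical reconstruction.
#'
#' @param m an `mf_morphology`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_swc <- function(m, path) {
  s <- m$sections
  n <- nrow(s)
  # node ids: 2 per section (start, end); start of root is the SWC root
  origin_x <- numeric(n)
  branch_y <- seq_len(n) * 5
  lines <- character(0)
  node <- 0L
  start_node <- integer(n)
  end_node <- integer(n)
  for (i in seq_len(n)) {
    pid <- s$parent_id[i]
    if (is.na(pid)) {
      x0 <- 0
      par_node <- -1L
    } else {
      p <- match(pid, s$id)
      x0 <- origin_x[p] + s$parent_pos[i] * s$length[p]
      par_node <- end_node[p]
    }
    origin_x[i] <- x0
    ty <- .swc_type(s$kind[i])
    node <- node + 1L
    start_node[i] <- node
    lines <- c(lines, sprintf("%d %d %.3f %.3f 0 %.4f %d", node, ty, x0,
                              branch_y[i], s$diam_prox[i] / 2, par_node))
    node <- node + 1L
    end_node[i] <- node
    lines <- c(lines, sprintf("%d %d %.3f %.3f 0 %.4f %d", node, ty,
                              x0 + s$length[i], branch_y[i],
                              s$diam_dist[i] / 2, start_node[i]))
  }
  writeLines(c("# SWC export (abstract coordinates; see docs)", lines), path)
  invisible(path)
}

#' Read and validate an experiment configuration file
#'
#' YAML schema: optional keys `parameter_set`, `protocol`, `overrides`
#' (merged into the parameter set), `output_dir`, `dt_ms`, `seed`.  Unknown
#' top-level keys are rejected.
#'
#' @param path YAML file.
#' @return list with the resolved `params` and the remaining settings.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  known <- c("parameter_set", "protocol", "overrides", "output_dir", "dt_ms",
             "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("schema violation: unknown config keys: ",
         paste(unknown, collapse = ", "))
  }
  params <- default_params(cfg$parameter_set %||% "default-calibrated-v1")
  if (!is.null(cfg$overrides)) params <- modifyList(params, cfg$overrides)
  if (!is.null(cfg$dt_ms)) params$sim$dt_ms <- cfg$dt_ms
  list(params = params, protocol = cfg$protocol,
       output_dir = cfg$output_dir %||% ".", seed = cfg$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write experiment metrics as JSON (with the resolved configuration)
#' @param metrics named list of scalar metrics.
#' @param params the resolved parameter set (embedded for provenance).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(metrics, params, path) {
  jsonlite::write_json(list(metrics = metrics, resolved_params = params),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
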