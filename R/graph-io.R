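#' Read and write neurite graphs
#'
#' The native format is JSON with top-level keys `meta`, `nodes`
#' (id, role) and `segments` (id, source, target, length_um,
#' velocity_m_per_s, refractory_ms, channel_spacing_um, dissipation_per_um,
#' activation_threshold, myelinated). Output is canonical — rows sorted by
#' id, fixed column order, full-precision floats — so writing the same graph
#' twice is byte-identical and `readNeuriteGraph(writeNeuriteGraph(g))`
#' reproduces `g` exactly.
#'
#' SWC import reads the standard 7-column morphology format
#' (id, type, x, y, z, radius, parent; `#` comments), mapping each
#' parent-child link to a directed segment whose length is the Euclidean
#' distance between the sample coordinates (um). The radius column is
#' ignored; all segments get `dynamics`. The root becomes ENTRY, leaves
#' TERMINAL, multi-child nodes BRANCH, the rest PASS.
#'
#' @param path file path.
#' @param format `"json"` (native) or `"swc"`.
#' @param dynamics [MembraneDynamics-class] assigned to SWC segments.
#' @param g a [NeuriteGraph-class].
#' @return `readNeuriteGraph` returns a [NeuriteGraph-class];
#'   `writeNeuriteGraph` invisibly returns `path`.
#' @examples
#' f <- tempfile(fileext = ".json")
#' writeNeuriteGraph(generateChain(3, 50), f)
#' g <- readNeuriteGraph(f)
#' @export
readNeuriteGraph <- function(path, format = c("json", "swc"),
                             dynamics = membraneDynamics()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "swc") return(.readSWC(path, dynamics))
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (!all(c("nodes", "segments") %in% names(obj)))
    stop("parse error in ", path,
         ": native graph JSON needs top-level 'nodes' and 'segments'",
         call. = FALSE)
  nodes <- as.data.frame(obj$nodes, stringsAsFactors = FALSE)
  segs <- as.data.frame(obj$segments, stringsAsFactors = FALSE)
  meta <- if (is.null(obj$meta)) list() else as.list(obj$meta)
  neuriteGraph(nodes, segs, meta = meta)
}

.canonicalGraph <- function(g) {
  nd <- g@nodes[order(g@nodes$id), c("id", "role"), drop = FALSE]
  rownames(nd) <- NULL
  sg <- g@segments[order(g@segments$id), .SEGMENT_COLS, drop = FALSE]
  rownames(sg) <- NULL
  meta <- g@meta
  if (length(meta)) meta <- meta[order(names(meta))]
  list(meta = meta, nodes = nd, segments = sg)
}

#' @rdname readNeuriteGraph
#' @export
writeNeuriteGraph <- function(g, path) {
  stopifnot(is(g, "NeuriteGraph"))
  can <- .canonicalGraph(g)
  json <- jsonlite::toJSON(can, dataframe = "rows", digits = NA,
                           auto_unbox = TRUE, pretty = 2, na = "null")
  writeLines(json, path)
  invisible(path)
}

.readSWC <- function(path, dynamics) {
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lineNo <- which(keep)
  if (!any(keep)) stop("parse error in ", path, ": no SWC samples",
                       call. = FALSE)
  parts <- strsplit(trimws(raw[keep]), "\\s+")
  bad <- which(vapply(parts, length, 1L) != 7L)
  if (length(bad))
    stop("parse error in ", path, " at line ", lineNo[bad[1]],
         ": expected 7 columns (id type x y z radius parent)", call. = FALSE)
  m <- do.call(rbind, lapply(parts, as.numeric))
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1, any))[1]
    stop("parse error in ", path, " at line ", lineNo[bad],
         ": non-numeric field", call. = FALSE)
  }
  df <- data.frame(id = m[, 1], x = m[, 3], y = m[, 4], z = m[, 5],
                   parent = m[, 7])
  if (anyDuplicated(df$id))
    stop("SWC validation: duplicate sample ids in ", path, call. = FALSE)
  orphan <- df$parent != -1 & !(df$parent %in% df$id)
  if (any(orphan))
    stop("SWC validation: sample ", df$id[which(orphan)[1]],
         " references missing parent ", df$parent[which(orphan)[1]],
         call. = FALSE)
  child <- df[df$parent != -1, , drop = FALSE]
  if (!nrow(child))
    stop("SWC validation: no parent links, cannot form segments",
         call. = FALSE)
  nodeId <- function(i) sprintf("n%d", as.integer(i))
  pidx <- match(child$parent, df$id)
  len <- sqrt((child$x - df$x[pidx])^2 + (child$y - df$y[pidx])^2 +
              (child$z - df$z[pidx])^2)
  if (any(len <= 0))
    stop("SWC validation: zero-length segment (coincident samples)",
         call. = FALSE)
  segs <- do.call(rbind, lapply(seq_len(nrow(child)), function(i)
    .segmentRow(sprintf("swc%d", as.integer(child$id[i])),
                nodeId(child$parent[i]), nodeId(child$id[i]), len[i],
                dynamics)))
  ig <- igraph::graph_from_data_frame(segs[, c("source", "target")],
                                      directed = TRUE,
                                      vertices = nodeId(df$id))
  if (!igraph::is_dag(ig))
    stop("SWC validation: parent links contain a cycle", call. = FALSE)
  nOut <- table(factor(segs$source, levels = nodeId(df$id)))
  role <- ifelse(df$parent == -1, "ENTRY",
                 ifelse(nOut[nodeId(df$id)] == 0L, "TERMINAL",
                        ifelse(nOut[nodeId(df$id)] >= 2L, "BRANCH", "PASS")))
  nodes <- data.frame(id = nodeId(df$id), role = as.character(role),
                      stringsAsFactors = FALSE)
  neuriteGraph(nodes, segs, meta = list(source = "swc"))
}

#' Read and write stimulus schedules
#'
#' CSV with header `node_id,time_s,label`. Malformed rows raise a parse
#' error naming the offending line.
#'
#' @param path file path.
#' @param s a [StimulusSchedule-class].
#' @return `readStimuli` returns a [StimulusSchedule-class]; `writeStimuli`
#'   invisibly returns `path`.
#' @export
readStimuli <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(NA, "character", NA))
  if (!all(c("node_id", "time_s", "label") %in% names(df)))
    stop("parse error in ", path,
         ": header must be node_id,time_s,label", call. = FALSE)
  t <- suppressWarnings(as.numeric(df$time_s))
  if (anyNA(t)) {
    bad <- which(is.na(t))[1]
    stop("parse error in ", path, " at line ", bad + 1L,
         ": time_s is not numeric ('", df$time_s[bad], "')", call. = FALSE)
  }
  stimulusSchedule(df$node_id, t, df$label)
}

#' @rdname readStimuli
#' @export
writeStimuli <- function(s, path) {
  stopifnot(is(s, "StimulusSchedule"))
  utils::write.csv(s@stimuli, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
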