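# Readers and writers for the plain-text interchange formats: TSV edge lists
# (generic and STRING protein-links dialect), GMT gene-set files, two-column
# ID-mapping and publication-count tables. All are tab-delimited UTF-8 with
# '#' comment lines ignored; STRING files may be space-delimited.

.readLinesClean <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  list(lines = lines[keep], lineno = which(keep))
}

# generic files are strictly tab-delimited (fine type labels contain
# spaces); the STRING protein-links dialect is whitespace-delimited
.splitFields <- function(lines) strsplit(lines, "\t")
.splitFieldsWs <- function(lines) strsplit(trimws(lines), "[\t ]+")

#' Read a global network from a TSV edge list
#'
#' Two dialects are supported. \code{generic_tsv} rows are
#' \code{node_a <tab> node_b <tab> fine_type [<tab> score]};
#' \code{string_links} is the STRING protein-links layout
#' (\code{protein1 protein2 combined_score}, header line allowed), whose
#' edges all receive fine type \code{"interaction"}. Duplicate
#' (pair, fine type) rows collapse to one keeping the maximum score;
#' self-loop rows are dropped and counted in \code{metadata}.
#'
#' @param path file path.
#' @param dialect \code{"generic_tsv"} or \code{"string_links"}.
#' @return A \linkS4class{GlobalNetwork}.
#' @export
readEdgeList <- function(path, dialect = c("generic_tsv", "string_links")) {
  dialect <- match.arg(dialect)
  dat <- .readLinesClean(path)
  fields <- if (dialect == "string_links") .splitFieldsWs(dat$lines)
            else .splitFields(dat$lines)
  if (dialect == "string_links" && length(fields) &&
      identical(tolower(fields[[1]][1]), "protein1"))
    { fields <- fields[-1]; dat$lineno <- dat$lineno[-1] }
  if (!length(fields)) stop("no data rows in ", path, call. = FALSE)
  nf <- lengths(fields)
  if (dialect == "generic_tsv") {
    bad <- which(nf < 3L)
    if (length(bad))
      stop("malformed row (need >= 3 fields) at line ", dat$lineno[bad[1]],
           " of ", path, call. = FALSE)
    a <- vapply(fields, `[`, "", 1L)
    b <- vapply(fields, `[`, "", 2L)
    type <- vapply(fields, `[`, "", 3L)
    hasScore <- nf >= 4L
    if (all(hasScore)) {
      score <- suppressWarnings(as.integer(vapply(fields, `[`, "", 4L)))
      if (anyNA(score))
        stop("non-integer score at line ", dat$lineno[which(is.na(score))[1]],
             " of ", path, call. = FALSE)
    } else if (any(hasScore)) {
      stop("mixed scored/unscored rows; first unscored at line ",
           dat$lineno[which(!hasScore)[1]], " of ", path, call. = FALSE)
    } else score <- NULL
  } else {
    bad <- which(nf < 3L)
    if (length(bad))
      stop("malformed STRING row at line ", dat$lineno[bad[1]], " of ", path,
           call. = FALSE)
    a <- vapply(fields, `[`, "", 1L)
    b <- vapply(fields, `[`, "", 2L)
    type <- "interaction"
    score <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
    if (anyNA(score))
      stop("non-integer combined_score at line ",
           dat$lineno[which(is.na(score))[1]], " of ", path, call. = FALSE)
  }
  net <- globalNetwork(a, b, type, score)
  if (net@metadata$droppedSelfLoops > 0)
    message("dropped ", net@metadata$droppedSelfLoops, " self-loop row(s)")
  net
}

#' Write a global network as a generic TSV edge list
#'
#' @param net a \linkS4class{GlobalNetwork}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeEdgeList <- function(net, path) {
  df <- edgeTable(net)
  cols <- c("a", "b", "type", if (net@scored) "score")
  lines <- do.call(paste, c(unname(df[cols]), sep = "\t"))
  writeLines(c(paste0("# ", paste(cols, collapse = "\t")), lines), path)
  invisible(path)
}

#' Keep only edges at or above a confidence score threshold
#'
#' Standard STRING-style cutoffs are 150, 400, 700 and 900. Nodes are
#' retained even when they become isolated (isolation matters downstream:
#' isolated nodes leave the degree-matched sampling universe).
#'
#' @param net a scored \linkS4class{GlobalNetwork}.
#' @param threshold integer; edges with \code{score >= threshold} survive.
#' @return A \linkS4class{GlobalNetwork} on the same node set.
#' @export
applyScoreThreshold <- function(net, threshold) {
  stopifnot(is(net, "GlobalNetwork"), threshold >= 0)
  if (threshold == 0) return(net)
  if (!net@scored)
    stop("network is unscored; a score threshold cannot be applied",
         call. = FALSE)
  keep <- which(net@edgeScore >= threshold)
  initialize(net, edgeA = net@edgeA[keep], edgeB = net@edgeB[keep],
             edgeType = net@edgeType[keep], edgeCoarse = net@edgeCoarse[keep],
             edgeScore = net@edgeScore[keep])
}

#' Read a two-column ID-mapping table (input ID -> node ID)
#'
#' @param path TSV file path.
#' @return Named character vector: \code{mapping[inputID] == nodeID}.
#' @export
readIdMapping <- function(path) {
  dat <- .readLinesClean(path)
  fields <- .splitFields(dat$lines)
  bad <- which(lengths(fields) < 2L)
  if (length(bad))
    stop("malformed mapping row at line ", dat$lineno[bad[1]], call. = FALSE)
  stats::setNames(vapply(fields, `[`, "", 2L), vapply(fields, `[`, "", 1L))
}

#' Resolve a vector of input IDs against a global network
#'
#' IDs are translated through \code{mapping} when one is supplied, then
#' intersected with the network's node set. Unmapped IDs are kept on the
#' result, never silently dropped.
#'
#' @param ids character vector of input IDs.
#' @param net a \linkS4class{GlobalNetwork}.
#' @param mapping optional named character vector (see
#'   \code{\link{readIdMapping}}).
#' @return A \linkS4class{GeneSet}.
#' @export
geneSet <- function(ids, net, mapping = NULL) {
  ids <- as.character(ids)
  uniq <- unique(ids)
  translated <- if (is.null(mapping)) uniq else unname(mapping[uniq])
  hit <- !is.na(translated) & translated %in% net@nodes
  mapped <- unique(translated[hit])
  unmapped <- uniq[!hit]
  if (!length(mapped))
    stop("none of the ", length(uniq), " input IDs mapped into the network; ",
         "check the ID namespace (a gene-to-protein mapping table may be ",
         "required)", call. = FALSE)
  new("GeneSet", rawIds = ids, mappedNodes = mapped, unmappedIds = unmapped)
}

#' Read a gene set from a plain ID list or single-row GMT file
#'
#' @param path file with one ID per line, or one GMT row
#'   (\code{name <tab> description <tab> members...}).
#' @param net a \linkS4class{GlobalNetwork}.
#' @param mapping optional ID-mapping table.
#' @return A \linkS4class{GeneSet}.
#' @export
readGeneSet <- function(path, net, mapping = NULL) {
  dat <- .readLinesClean(path)
  if (!length(dat$lines)) stop("no IDs in ", path, call. = FALSE)
  fields <- strsplit(dat$lines, "\t")
  ids <- if (length(fields) == 1L && length(fields[[1]]) >= 3L)
    fields[[1]][-(1:2)]
  else
    trimws(vapply(fields, `[`, "", 1L))
  geneSet(ids[nzchar(ids)], net, mapping)
}

#' Read a GMT file
#'
#' @param path GMT file: \code{name <tab> description <tab> members...}.
#' @return Named list of character member vectors.
#' @export
readGmt <- function(path) {
  dat <- .readLinesClean(path)
  fields <- strsplit(dat$lines, "\t")
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("GMT row with fewer than 3 fields at line ", dat$lineno[bad[1]],
         " of ", path, call. = FALSE)
  stats::setNames(lapply(fields, function(f) f[-(1:2)]),
                  vapply(fields, `[`, "", 1L))
}

#' Write a named list of ID vectors as GMT
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector (recycled).
#' @return \code{path}, invisibly.
#' @export
writeGmt <- function(sets, path, descriptions = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  descriptions <- rep_len(descriptions, length(sets))
  lines <- mapply(function(nm, d, members)
    paste(c(nm, d, members), collapse = "\t"),
    names(sets), descriptions, sets)
  writeLines(unname(lines), path)
  invisible(path)
}

#' Read annotations (GMT of processes) as a node-to-process table
#'
#' @param path GMT file: one row per process, members are node IDs.
#' @return Named list: node ID -> character vector of process IDs.
#' @export
readAnnotations <- function(path) {
  gmt <- readGmt(path)
  node <- unlist(gmt, use.names = FALSE)
  proc <- rep(names(gmt), lengths(gmt))
  lapply(split(proc, node), unique)
}

#' Read a two-column publication-count table
#'
#' @param path TSV: node ID, non-negative integer count.
#' @return Named integer vector.
#' @export
readPubCounts <- function(path) {
  dat <- .readLinesClean(path)
  fields <- .splitFields(dat$lines)
  bad <- which(lengths(fields) < 2L)
  if (length(bad))
    stop("malformed publication-count row at line ", dat$lineno[bad[1]],
         call. = FALSE)
  counts <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  if (anyNA(counts) || any(counts < 0))
    stop("publication counts must be non-negative integers", call. = FALSE)
  stats::setNames(counts, vapply(fields, `[`, "", 1L))
}
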