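# Edge-list TSV dialect: three tab-separated columns (side-A vertex,
# side-B vertex, weight), '#' comment lines, optional header. Association
# tables carry p-values instead of similarities; they are mapped onto the
# similarity scale as -log10(p) with the conventional 0.05 significance
# threshold (-log10(0.05) ~ 1.301).

#' Read a weighted edge-list TSV
#'
#' @param path file path.
#' @param pvalue if TRUE the third column holds p-values; weights become
#'   `-log10(p)`.
#' @return data.frame with columns `u`, `v`, `weight`.
#' @export
read_edge_tsv <- function(path, pvalue = FALSE) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) {
    return(data.frame(u = character(0), v = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    stop("parse error at line ", lineno[bad[1L]],
         ": expected 3 tab-separated columns", call. = FALSE)
  }
  first_w <- suppressWarnings(as.numeric(fields[[1L]][3L]))
  if (is.na(first_w)) {           # header line
    fields <- fields[-1L]
    lineno <- lineno[-1L]
  }
  if (!length(fields)) {
    return(data.frame(u = character(0), v = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE))
  }
  u <- vapply(fields, `[[`, character(1), 1L)
  v <- vapply(fields, `[[`, character(1), 2L)
  w <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  if (anyNA(w)) {
    stop("parse error at line ", lineno[which(is.na(w))[1L]],
         ": non-numeric weight", call. = FALSE)
  }
  if (pvalue) {
    if (any(w <= 0 | w > 1)) {
      stop("parse error: p-values must lie in (0, 1]", call. = FALSE)
    }
    w <- -log10(w)
  }
  data.frame(u = u, v = v, weight = w, stringsAsFactors = FALSE)
}

#' Write a graph as an edge-list TSV
#'
#' @param g a [bipartite_graph()] object.
#' @param path output file path.
#' @param scale "shifted" writes stored weights; "raw" adds `threshold`
#'   back.
#' @param threshold the shift to undo when `scale = "raw"`.
#' @return invisibly, the path.
#' @export
write_edge_tsv <- function(g, path, scale = c("shifted", "raw"),
                           threshold = 0) {
  scale <- match.arg(scale)
  e <- edges_of(g)
  if (scale == "raw") e$weight <- e$weight + threshold
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# side_a\tside_b\tweight", con)
  if (nrow(e)) {
    writeLines(sprintf("%s\t%s\t%.10g", e$u, e$v, e$weight), con)
  }
  invisible(path)
}

#' The -log10 significance threshold for p-value graphs
#'
#' @param alpha significance level (default 0.05).
#' @return `-log10(alpha)`; 1.30103 at the default, commonly printed 1.301.
#' @export
pvalue_threshold <- function(alpha = 0.05) {
  -log10(alpha)
}

#' Solve an edge-list file end to end
#'
#' Reads the TSV, builds the graph, reduces, dispatches each component
#' ([solve_graph()]), and optionally writes three files:
#' `<prefix>_edits.tsv` (op, u, v, cost, default_weight flag),
#' `<prefix>_clusters.tsv` (cluster id, vertex, side) and
#' `<prefix>_report.json`. Insertions of pairs absent from the input are
#' reported at cost `|default_weight|` and flagged, so putative
#' associations can be audited.
#'
#' @param path input edge-list TSV.
#' @param algorithm "auto", "exact" or "heuristic".
#' @param threshold similarity threshold (default 0; with `pvalue = TRUE`
#'   defaults to [pvalue_threshold()]).
#' @param default_weight shifted weight of unlisted pairs (default -1).
#' @param pvalue treat the weight column as p-values.
#' @param exact_size_cap,node_cap,time_limit solver limits, see
#'   [solve_graph()].
#' @param out_prefix path prefix for output files, or NULL to skip writing.
#' @param quiet suppress progress messages.
#' @return a [solution][bce_solution] with attribute `"report"` (data.frame
#'   of per-component vertex/edge counts, algorithm, cost, optimality,
#'   nodes, seconds).
#' @export
solve_file <- function(path, algorithm = c("auto", "exact", "heuristic"),
                       threshold = NULL, default_weight = -1,
                       pvalue = FALSE, exact_size_cap = 40L,
                       node_cap = Inf, time_limit = Inf,
                       out_prefix = NULL, quiet = FALSE) {
  algorithm <- match.arg(algorithm)
  if (is.null(threshold)) {
    threshold <- if (pvalue) pvalue_threshold() else 0
  }
  records <- read_edge_tsv(path, pvalue = pvalue)
  g <- build_graph(records, threshold = threshold,
                   default_weight = default_weight)
  sol <- solve_graph(g, algorithm = algorithm,
                     exact_size_cap = exact_size_cap, node_cap = node_cap,
                     time_limit = time_limit, quiet = quiet)
  if (!is.null(out_prefix)) {
    write_solution_files(sol, out_prefix)
  }
  sol
}

write_solution_files <- function(sol, prefix) {
  ed <- sol$edits
  utils::write.table(
    data.frame(op = ed$op, u = ed$u, v = ed$v,
               cost = sprintf("%.10g", ed$cost),
               default_weight = ed$default_weight),
    file = paste0(prefix, "_edits.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    sol$clusters[, c("cluster", "vertex", "side")],
    file = paste0(prefix, "_clusters.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  rep <- attr(sol, "report")
  payload <- list(
    total_cost = sol$total_cost,
    n_edits = nrow(sol$edits),
    n_clusters = length(unique(sol$clusters$cluster)),
    optimal = isTRUE(sol$optimal),
    components = rep)
  jsonlite::write_json(payload, paste0(prefix, "_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(prefix)
}

#' Verify a written solution against its input
#'
#' Re-reads the input edge list and the edits/clusters files, re-applies
#' the edits and checks that (1) the edited graph is a disjoint union of
#' bi-cliques, (2) no pair is edited twice, and (3) the clusters file
#' matches the edited graph's components.
#'
#' @param input input edge-list TSV.
#' @param edits_file,clusters_file the solver's output files.
#' @param threshold,default_weight,pvalue as used when solving.
#' @return TRUE invisibly on success; otherwise an error describing the
#'   first violated check.
#' @export
check_solution_files <- function(input, edits_file, clusters_file,
                                 threshold = NULL, default_weight = -1,
                                 pvalue = FALSE) {
  if (is.null(threshold)) threshold <- if (pvalue) pvalue_threshold() else 0
  records <- read_edge_tsv(input, pvalue = pvalue)
  g <- build_graph(records, threshold = threshold,
                   default_weight = default_weight)
  ed <- utils::read.delim(edits_file, stringsAsFactors = FALSE,
                          colClasses = c(op = "character", u = "character",
                                         v = "character"))
  cl <- utils::read.delim(clusters_file, stringsAsFactors = FALSE,
                          colClasses = c(vertex = "character"))
  if (anyDuplicated(ed[, c("u", "v")]) > 0L) {
    stop("check failed: a pair is edited twice", call. = FALSE)
  }
  edited <- apply_edits(g, ed)
  if (!is_transitive(edited)) {
    stop("check failed: edited graph is not a union of bi-cliques",
         call. = FALSE)
  }
  memb <- component_membership(edited)
  got <- split(names(memb), memb)
  want <- split(cl$vertex, cl$cluster)
  norm <- function(parts) {
    parts <- lapply(parts, sort_lex)
    unname(parts[order(vapply(parts, `[`, character(1), 1L),
                       method = "radix")])
  }
  if (!identical(norm(got), norm(want))) {
    stop("check failed: clusters file does not match edited components",
         call. = FALSE)
  }
  invisible(TRUE)
}
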