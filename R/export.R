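#' Export a flux map as a graph file
#'
#' Writes the bipartite metabolite/reaction graph with flux magnitudes as
#' edge widths, in DOT or GraphML format (a plain-text stand-in for
#' dedicated flux-map renderers). Edges follow the realised direction of
#' each flux (a negative flux through a reversible reaction reverses its
#' arrows); zero-flux reactions are kept, drawn at the minimum width. When
#' two solutions are given, an edge `color` attribute classifies each
#' reaction by the sign of its percent change (`red` increased, `blue`
#' decreased, `grey` unchanged/undefined), mirroring the conventional
#' coloring of comparative flux maps.
#'
#' @param network a `vf_network`.
#' @param solutions a `vf_solution` or a list of two (control, treatment).
#' @param path output file.
#' @param format `"dot"` or `"graphml"`.
#' @param min_width minimum edge width attribute (default 0.2).
#' @param max_width maximum edge width attribute (default 8).
#' @param dead_band percent dead-band for the two-solution coloring.
#' @return `path`, invisibly.
#' @export
export_flux_map <- function(network, solutions, path,
                            format = c("dot", "graphml"),
                            min_width = 0.2, max_width = 8, dead_band = 5) {
  format <- match.arg(format)
  validate_network(network)
  if (inherits(solutions, "vf_solution")) {
    sol <- solutions; cmp <- NULL
  } else if (is.list(solutions) && length(solutions) == 2L) {
    sol <- solutions[[1]]
    cmp <- percent_change_map(solutions[[1]], solutions[[2]], network,
                              dead_band = dead_band)
  } else vf_stop("solutions must be one vf_solution or a list of two")

  v <- as.numeric(sol$v)
  rids <- reaction_ids(network)
  mids <- metabolite_ids(network)
  vmax <- max(abs(v), 0)
  widths <- if (vmax > 0) pmax(min_width, max_width * abs(v) / vmax) else rep(min_width, length(v))

  edges <- character(0); ewidth <- numeric(0); ecolor <- character(0)
  for (j in seq_along(network$reactions)) {
    st <- network$reactions[[j]]$stoich
    dir <- if (v[j] < 0) -1 else 1
    col <- if (is.null(cmp)) "black" else switch(cmp$class[j],
      increased = "red", decreased = "blue", "grey")
    for (k in seq_along(st)) {
      from_met <- dir * st[k] < 0
      e <- if (from_met) c(names(st)[k], rids[j]) else c(rids[j], names(st)[k])
      edges <- c(edges, e)
      ewidth <- c(ewidth, widths[j])
      ecolor <- c(ecolor, col)
    }
  }

  g <- igraph::make_empty_graph(directed = TRUE)
  g <- igraph::add_vertices(g, length(mids), name = mids, type = "metabolite",
                            label = mids)
  g <- igraph::add_vertices(g, length(rids), name = rids, type = "reaction",
                            label = rids, flux = v)
  g <- igraph::add_edges(g, edges)
  igraph::E(g)$width <- ewidth
  igraph::E(g)$color <- ecolor
  igraph::write_graph(g, path, format = format)
  invisible(path)
}

#' Write a flux solution TSV
#'
#' Columns `reaction_id  flux  lb  ub  at_bound(0/1)`, sorted by reaction
#' id for deterministic output.
#'
#' @param solution a `vf_solution`.
#' @param problem the `vf_problem` it solved.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_flux_tsv <- function(solution, problem, path) {
  df <- solution_table(solution, problem)
  df <- df[order(df$reaction_id), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a flux solution TSV written by [write_flux_tsv()]
#'
#' @param path TSV path.
#' @return data.frame with `reaction_id`, `flux`, `lb`, `ub`, `at_bound`.
#' @export
read_flux_tsv <- function(path) {
  if (!file.exists(path)) vf_stop("flux table not found: %s", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("reaction_id", "flux", "lb", "ub", "at_bound")
  if (!all(req %in% names(d)))
    vf_stop("%s: expected columns %s", path, paste(req, collapse = ", "))
  d
}

#' Write a comparison CSV
#'
#' Columns `reaction_id,flux_control,flux_treatment,percent_change,class`,
#' sorted by reaction id.
#'
#' @param comparison a `vf_comparison` from [percent_change_map()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(comparison, path) {
  df <- comparison[order(comparison$reaction_id),
                   c("reaction_id", "flux_control", "flux_treatment",
                     "percent_change", "class")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# deterministic JSON run manifest: inputs are identified by content hash so
# that re-runs with identical inputs are byte-identical (no timestamps)
write_manifest <- function(path, command, inputs = character(0), options = list()) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  obj <- list(tool = "vitisflux",
              version = as.character(utils::packageVersion("vitisflux")),
              command = command,
              input_md5 = hashes,
              options = options)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
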