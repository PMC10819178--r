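# Food-source -> food-compound -> drug network of concentration-altering
# drug-food interactions, with GraphML/SIF export via igraph.

#' Filter DFIs that alter drug concentrations
#'
#' Retains validated DFI records whose type belongs to the eight
#' concentration-altering types (absorption 1/2, bioavailability 4/5,
#' metabolism 6/7, serum concentration 9/10) and whose sentence subject is
#' the food compound. Each record is labelled `decrease` (types 1, 4, 7, 9)
#' or `increase` (types 2, 5, 6, 10) of the drug concentration.
#'
#' @param records Validated DFI records tibble.
#' @param food_ids Food compound IDs.
#' @return The retained records with `direction`, `food_id` and `drug_id`
#'   columns added.
#' @export
filter_concentration_dfis <- function(records, food_ids) {
  ct <- concentration_types()
  keep <- records$type_id %in% ct$all & records$subject_id %in% food_ids
  out <- records[keep, , drop = FALSE]
  out$direction <- ifelse(out$type_id %in% ct$decrease, "decrease", "increase")
  out$food_id <- out$subject_id
  out$drug_id <- out$object_id
  out
}

#' Richest food sources of a compound
#'
#' Sources ranked by their reported content of the compound (maximum amount
#' per source by default, mean with `rank = "mean"`), truncated at `k`; ties
#' are broken by lexicographic source name.
#'
#' @param compound_id Food compound ID.
#' @param contents Content tibble (`source_id`, `source_name`,
#'   `compound_id`, `amount_mg_per_100g`).
#' @param k Maximum number of sources. Default 10.
#' @param rank Aggregation over duplicate content rows: `"max"` (default) or
#'   `"mean"`.
#' @return Tibble with `source_id`, `source_name`, `amount`, at most `k`
#'   rows; empty if the compound is absent from the table.
#' @export
top_sources <- function(compound_id, contents, k = 10L,
                        rank = c("max", "mean")) {
  rank <- match.arg(rank)
  rows <- contents[contents$compound_id == compound_id, , drop = FALSE]
  if (nrow(rows) == 0) {
    return(tibble::tibble(source_id = character(0), source_name = character(0),
                          amount = numeric(0)))
  }
  agg <- dplyr::summarise(
    dplyr::group_by(rows, .data$source_id, .data$source_name),
    amount = if (rank == "max") max(.data$amount_mg_per_100g) else
      mean(.data$amount_mg_per_100g),
    .groups = "drop")
  agg <- agg[order(-agg$amount, agg$source_name), ]
  utils::head(agg, k)
}

#' Build the food-source/compound/drug interaction network
#'
#' Nodes are food sources, food compounds and drugs; `contains` edges link
#' each compound's top-`k` sources to the compound (weighted by amount) and
#' `alters` edges link compounds to drugs (labelled with direction and type).
#' Only entities on retained edges appear (no orphan nodes).
#'
#' @param filtered Records from [filter_concentration_dfis()].
#' @param contents Food content tibble.
#' @param k Sources per compound. Default 10.
#' @param names Optional named vector mapping IDs to display names.
#' @return A list of class `ddi_dfi_network` with `nodes`, `edges` and an
#'   igraph `graph`.
#' @export
build_network <- function(filtered, contents, k = 10L, names = NULL) {
  if (nrow(filtered) == 0) {
    nodes <- tibble::tibble(id = character(0), node_type = character(0),
                            label = character(0))
    edges <- tibble::tibble(from = character(0), to = character(0),
                            edge_type = character(0), weight = numeric(0),
                            direction = character(0), type_id = integer(0))
    g <- igraph::make_empty_graph(directed = TRUE)
    return(structure(list(nodes = nodes, edges = edges, graph = g),
                     class = "ddi_dfi_network"))
  }
  alters <- tibble::tibble(from = filtered$food_id, to = filtered$drug_id,
                           edge_type = "alters", weight = filtered$score,
                           direction = filtered$direction,
                           type_id = filtered$type_id)
  contains <- dplyr::bind_rows(lapply(unique(filtered$food_id), function(f) {
    ts <- top_sources(f, contents, k)
    if (nrow(ts) == 0) return(NULL)
    tibble::tibble(from = ts$source_id, to = f, edge_type = "contains",
                   weight = ts$amount, direction = NA_character_,
                   type_id = NA_integer_)
  }))
  edges <- dplyr::bind_rows(contains, alters)
  src_names <- unique(contents[, c("source_id", "source_name")])
  node_ids <- unique(c(edges$from, edges$to))
  node_type <- ifelse(node_ids %in% filtered$food_id, "food_compound",
                      ifelse(node_ids %in% src_names$source_id, "food_source",
                             "drug"))
  label <- node_ids
  if (!is.null(names)) {
    hit <- node_ids %in% base::names(names)
    label[hit] <- names[node_ids[hit]]
  }
  sn <- stats::setNames(src_names$source_name, src_names$source_id)
  label[node_type == "food_source"] <- sn[node_ids[node_type == "food_source"]]
  nodes <- tibble::tibble(id = node_ids, node_type = node_type, label = label)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "ddi_dfi_network")
}

#' Subnetwork around a set of drugs
#'
#' Restricts the network to `alters` edges pointing at the given drugs, the
#' food compounds on those edges and their `contains` sources (e.g. all S1P
#' receptor modulators, or all BTK inhibitors).
#'
#' @param network A `ddi_dfi_network`.
#' @param drug_ids Drug IDs to keep.
#' @return A `ddi_dfi_network`.
#' @export
subnetwork_by_drugs <- function(network, drug_ids) {
  stopifnot(inherits(network, "ddi_dfi_network"))
  alters <- network$edges[network$edges$edge_type == "alters" &
                            network$edges$to %in% drug_ids, , drop = FALSE]
  compounds <- unique(alters$from)
  contains <- network$edges[network$edges$edge_type == "contains" &
                              network$edges$to %in% compounds, , drop = FALSE]
  edges <- dplyr::bind_rows(contains, alters)
  nodes <- network$nodes[network$nodes$id %in% unique(c(edges$from, edges$to)), ]
  g <- if (nrow(edges) == 0) {
    igraph::make_empty_graph(directed = TRUE)
  } else {
    igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
  }
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "ddi_dfi_network")
}

#' Export a network as GraphML and SIF
#'
#' @param network A `ddi_dfi_network`.
#' @param graphml_path,sif_path Output paths (either may be `NULL`).
#' @return Invisibly, a list of written paths.
#' @export
export_network <- function(network, graphml_path = NULL, sif_path = NULL) {
  stopifnot(inherits(network, "ddi_dfi_network"))
  if (!is.null(graphml_path)) {
    igraph::write_graph(network$graph, graphml_path, format = "graphml")
  }
  if (!is.null(sif_path)) {
    rel <- ifelse(network$edges$edge_type == "contains", "contains",
                  paste0("alters_", network$edges$direction))
    writeLines(paste(network$edges$from, rel, network$edges$to, sep = "\t"),
               sif_path)
  }
  invisible(list(graphml = graphml_path, sif = sif_path))
}
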