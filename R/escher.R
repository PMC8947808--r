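# Escher-compatible JSON map export.

#' Export a network (and optional fit) as an Escher map
#'
#' Builds an Escher map-schema (1-0-0) document: a two-element list of map
#' metadata and map body, with one reaction entry per network reaction, one
#' metabolite node per species and a simple automatic grid layout. When a
#' fit is supplied, the estimated flux value is attached to each reaction's
#' `name` field so the map is self-describing when loaded.
#'
#' @param net an [MFANetwork-class].
#' @param fit optional [MFAFit-class]; its fluxes annotate the reactions.
#' @param mapName map name string.
#' @return a list (JSON-ready); serialize with [writeEscherMap()].
#' @export
exportEscher <- function(net, fit = NULL, mapName = "fluxnlp_map") {
  mets <- net@metabolites$name
  nm <- length(mets)
  ncol_ <- ceiling(sqrt(nm))
  nodes <- list()
  metNode <- character(0)
  nid <- 0L
  for (i in seq_along(mets)) {
    nid <- nid + 1L
    x <- 150 * ((i - 1) %% ncol_)
    y <- 150 * ((i - 1) %/% ncol_)
    nodes[[as.character(nid)]] <- list(
      node_type = "metabolite", x = x, y = y,
      bigg_id = mets[i], name = mets[i],
      label_x = x + 10, label_y = y + 10, node_is_primary = TRUE)
    metNode[mets[i]] <- as.character(nid)
  }
  reactionsOut <- list()
  segId <- 0L
  for (j in seq_along(net@reactions)) {
    r <- net@reactions[[j]]
    nid <- nid + 1L
    mid <- as.character(nid)   # midmarker node
    anchor <- metNode[[r$reactants[[1]]$met]]
    ax <- nodes[[anchor]]$x; ay <- nodes[[anchor]]$y
    nodes[[mid]] <- list(node_type = "midmarker", x = ax + 60, y = ay + 60)
    segments <- list()
    for (term in c(r$reactants, r$products)) {
      segId <- segId + 1L
      segments[[as.character(segId)]] <- list(
        from_node_id = mid, to_node_id = metNode[[term$met]],
        b1 = NULL, b2 = NULL)
    }
    coeffs <- c(lapply(r$reactants, function(t)
                  list(bigg_id = t$met, coefficient = -t$coeff)),
                lapply(r$products, function(t)
                  list(bigg_id = t$met, coefficient = t$coeff)))
    name <- r$id
    if (!is.null(fit) && r$id %in% names(fit@v))
      name <- sprintf("%s (flux %.4g)", r$id, fit@v[[r$id]])
    reactionsOut[[as.character(j)]] <- list(
      name = name, bigg_id = r$id,
      reversibility = isTRUE(r$reversible),
      label_x = ax + 70, label_y = ay + 70,
      gene_reaction_rule = "", genes = list(),
      metabolites = coeffs, segments = segments)
  }
  meta <- list(
    map_name = mapName,
    map_id = mapName,
    map_description = "Metabolic network map exported by fluxnlp",
    homepage = "https://escher.github.io",
    schema = "https://escher.github.io/escher/jsonschema/1-0-0#")
  list(meta,
       list(reactions = reactionsOut, nodes = nodes,
            text_labels = structure(list(), names = character(0)),
            canvas = list(x = -100, y = -100,
                          width = 150 * ncol_ + 200,
                          height = 150 * ceiling(nm / ncol_) + 200)))
}

#' @rdname exportEscher
#' @param path output file path.
#' @export
writeEscherMap <- function(net, fit = NULL, path, mapName = "fluxnlp_map") {
  doc <- exportEscher(net, fit, mapName)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}
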