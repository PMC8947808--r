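# Network-definition parser.
#
# Dialect: one reaction per line,
#   id: [coeff] M1 (abc) + M2 (d) -> [coeff] M3 (abcd)
# with '<->' marking reversible reactions, '#' starting comments and blank
# lines ignored. Lowercase letters in parentheses name the carbon atoms of
# each metabolite occurrence; product letters must be a permutation of
# reactant letters (carbon conservation). Metabolites without parentheses
# carry no tracked carbon. Roles, bounds, tracers, measurements and pool
# information live in a structured config (YAML text or R list).

parseReactionTerm <- function(term, rid) {
  term <- trimws(term)
  m <- regmatches(term, regexec(
    "^([0-9]*\\.?[0-9]+)?\\s*([A-Za-z0-9_.]+)\\s*(\\(([a-z]+)\\))?$", term))[[1]]
  if (length(m) == 0 || !nzchar(m[3]))
    stopf("reaction '%s': cannot parse term '%s'", rid, term)
  coeff <- if (nzchar(m[2])) as.numeric(m[2]) else 1
  atoms <- if (nzchar(m[5])) strsplit(m[5], "")[[1]] else character(0)
  list(met = m[3], coeff = coeff, atoms = atoms)
}

parseReactionLine <- function(line, lineno) {
  line <- sub("#.*$", "", line)
  if (!nzchar(trimws(line))) return(NULL)
  m <- regmatches(line, regexec("^\\s*([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", line))[[1]]
  if (length(m) == 0)
    stopf("line %d: expected 'id: reactants -> products'", lineno)
  rid <- m[2]
  body <- m[3]
  reversible <- grepl("<->", body, fixed = TRUE)
  sides <- strsplit(body, if (reversible) "<->" else "->", fixed = TRUE)[[1]]
  if (length(sides) != 2)
    stopf("line %d (reaction '%s'): missing or malformed arrow", lineno, rid)
  parseSide <- function(s) {
    terms <- strsplit(s, "+", fixed = TRUE)[[1]]
    terms <- terms[nzchar(trimws(terms))]
    lapply(terms, parseReactionTerm, rid = rid)
  }
  reactants <- parseSide(sides[1])
  products <- parseSide(sides[2])
  if (length(reactants) == 0 || length(products) == 0)
    stopf("line %d (reaction '%s'): both sides must be nonempty", lineno, rid)
  # carbon conservation: product letters are a permutation of reactant letters
  rl <- unlist(lapply(reactants, `[[`, "atoms"))
  pl <- unlist(lapply(products, `[[`, "atoms"))
  if (anyDuplicated(rl) || anyDuplicated(pl))
    stopf("reaction '%s': atom letters must be unique within each side", rid)
  if (!identical(sort(rl), sort(pl)))
    stopf("reaction '%s': unbalanced carbon atom map (reactant atoms '%s' vs product atoms '%s')",
          rid, paste(sort(rl), collapse = ""), paste(sort(pl), collapse = ""))
  list(id = rid, reversible = reversible, reactants = reactants,
       products = products, lb = NA_real_, ub = NA_real_, line = lineno)
}

#' Parse a metabolic network definition
#'
#' Reads a plain-text network definition (one reaction per line with carbon
#' atom transition maps, see Details) together with an optional structured
#' configuration carrying metabolite roles, flux bounds, tracer
#' specifications, flux/pool measurements and the natural 13C abundance.
#'
#' @details Each reaction line has the form
#' `id: A (abc) + B (d) -> C (abcd)`, with `<->` marking a reversible
#' reaction. The lowercase letters name carbon atoms: every product carbon
#' derives from the reactant carbon with the same letter, so the letters on
#' the two sides must be permutations of each other. Metabolite roles default
#' to `input` for species never produced, `output` for species never
#' consumed, and `balanced` otherwise; the config `metabolites` section can
#' override roles. Config keys: `metabolites` (named list with `role`),
#' `bounds` (named per reaction: `lb`, `ub`; for reversible reactions these
#' are net-flux bounds), `fixed` (named reaction values, encoded as
#' `lb = ub`), `flux_measurements` (list of `reaction`, `value`, `sd`),
#' `pools` (named per metabolite: `lb`, `ub`, `value`, `sd`),
#' `tracers` (list of mixture components: `substrate`, `fraction`,
#' `positions` as integer vector or `"U"`, `enrichment`), and
#' `nat_abundance` (default 0.0107).
#'
#' @param text character: the network definition, either a single string, a
#'   character vector of lines, or a file path.
#' @param config optional config as YAML text, a file path, or an R list.
#' @return an [MFANetwork-class] (reversible reactions flagged, not split).
#' @examples
#' net <- parseNetwork("v1: A (abc) -> B (abc)")
#' metabolites(net)
#' @export
parseNetwork <- function(text, config = NULL) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    text <- readLines(text)
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  rxns <- list()
  for (i in seq_along(lines)) {
    r <- parseReactionLine(lines[i], i)
    if (is.null(r)) next
    if (r$id %in% vapply(rxns, `[[`, character(1), "id"))
      stopf("duplicate reaction id '%s' (line %d)", r$id, i)
    rxns[[length(rxns) + 1L]] <- r
  }
  if (length(rxns) == 0) stopf("no reactions found in network definition")
  cfg <- readConfig(config)

  # metabolite table: carbon counts from atom maps, consistency enforced
  mets <- new.env(parent = emptyenv())
  produced <- character(0); consumed <- character(0)
  for (r in rxns) {
    for (side in c("reactants", "products")) {
      for (term in r[[side]]) {
        nc <- length(term$atoms)
        old <- mets[[term$met]]
        if (is.null(old)) assign(term$met, nc, envir = mets)
        else if (old != nc)
          stopf("metabolite '%s' has inconsistent carbon counts (%d vs %d, reaction '%s')",
                term$met, old, nc, r$id)
      }
    }
    consumed <- c(consumed, vapply(r$reactants, `[[`, character(1), "met"))
    produced <- c(produced, vapply(r$products, `[[`, character(1), "met"))
    if (r$reversible) { # either side can be produced/consumed
      produced <- c(produced, vapply(r$reactants, `[[`, character(1), "met"))
      consumed <- c(consumed, vapply(r$products, `[[`, character(1), "met"))
    }
  }
  nm <- sort(ls(mets))
  role <- ifelse(!(nm %in% produced), "input",
                 ifelse(!(nm %in% consumed), "output", "balanced"))
  metdf <- data.frame(name = nm,
                      n_carbons = vapply(nm, function(x) mets[[x]], numeric(1)),
                      role = role, stringsAsFactors = FALSE)
  for (mn in names(cfg$metabolites %||% list())) {
    if (!mn %in% metdf$name) stopf("config metabolite '%s' not in network", mn)
    r <- cfg$metabolites[[mn]]$role
    if (!is.null(r)) metdf$role[metdf$name == mn] <- r
  }
  rownames(metdf) <- NULL

  # bounds and fixed fluxes
  for (i in seq_along(rxns)) {
    id <- rxns[[i]]$id
    b <- cfg$bounds[[id]]
    rxns[[i]]$lb <- if (!is.null(b$lb)) b$lb else if (rxns[[i]]$reversible) -Inf else 0
    rxns[[i]]$ub <- if (!is.null(b$ub)) b$ub else Inf
    fx <- cfg$fixed[[id]]
    if (!is.null(fx)) { rxns[[i]]$lb <- fx; rxns[[i]]$ub <- fx }
  }

  fm <- cfg$flux_measurements %||% list()
  fluxMeas <- if (length(fm))
    data.frame(reaction = vapply(fm, `[[`, character(1), "reaction"),
               value = vapply(fm, `[[`, numeric(1), "value"),
               sd = vapply(fm, `[[`, numeric(1), "sd"), stringsAsFactors = FALSE)
  else data.frame(reaction = character(0), value = numeric(0), sd = numeric(0))
  bad <- setdiff(fluxMeas$reaction, vapply(rxns, `[[`, character(1), "id"))
  if (length(bad)) stopf("flux measurement references unknown reaction '%s'", bad[1])

  poolcfg <- cfg$pools %||% list()
  poolInfo <- data.frame(
    metabolite = names(poolcfg) %||% character(0),
    lb = vapply(poolcfg, function(p) p$lb %||% 1e-3, numeric(1)),
    ub = vapply(poolcfg, function(p) p$ub %||% 1e3, numeric(1)),
    value = vapply(poolcfg, function(p) p$value %||% NA_real_, numeric(1)),
    sd = vapply(poolcfg, function(p) p$sd %||% NA_real_, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(poolInfo) <- NULL
  bad <- setdiff(poolInfo$metabolite, metdf$name)
  if (length(bad)) stopf("pool config references unknown metabolite '%s'", bad[1])

  tracers <- cfg$tracers %||% list()
  for (tr in tracers) {
    if (!(tr$substrate %||% "") %in% metdf$name)
      stopf("tracer references unknown metabolite '%s'", tr$substrate %||% "?")
    if (!is.null(tr$enrichment) && (tr$enrichment < 0 || tr$enrichment > 1))
      stopf("tracer enrichment must lie in [0, 1]")
  }

  new("MFANetwork", metabolites = metdf, reactions = rxns,
      Rineq = NULL, bineq = numeric(0),
      fluxMeas = fluxMeas, poolInfo = poolInfo, tracers = tracers,
      natAbundance = cfg$nat_abundance %||% 0.0107, split = FALSE)
}

readConfig <- function(config) {
  if (is.null(config)) return(list())
  if (is.list(config)) return(config)
  if (length(config) == 1 && !grepl("\n", config) && file.exists(config))
    return(yaml::read_yaml(config))
  yaml::yaml.load(paste(config, collapse = "\n"))
}
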