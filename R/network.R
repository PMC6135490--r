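COMPARTMENTS <- c("extracellular", "cytosolic", "mitochondrial")

#' Construct a compartmentalised metabolic network
#'
#' A \code{metabolic_network} couples an ordered metabolite table with an
#' ordered reaction table.  Metabolites flagged \code{exchanged} are traded
#' with the blood (or, for cytosolic protons, deliberately left unbalanced)
#' and are excluded from the steady-state balance; all other metabolites are
#' internal and must have zero net production at steady state.
#'
#' @param metabolites data.frame with columns \code{id}, \code{name},
#'   \code{compartment} (one of extracellular/cytosolic/mitochondrial) and
#'   logical \code{exchanged}.
#' @param reactions data.frame with columns \code{id}, \code{name},
#'   \code{reversible} (logical), \code{subsystem}, and list columns
#'   \code{stoichiometry} (named numeric, negative = consumed) and
#'   \code{genes} (character vectors of HGNC symbols, possibly empty).
#' @return An object of class \code{metabolic_network}.
#' @export
metabolic_network <- function(metabolites, reactions) {
  metabolites$id <- as.character(metabolites$id)
  metabolites$exchanged <- as.logical(metabolites$exchanged)
  reactions$id <- as.character(reactions$id)
  reactions$reversible <- as.logical(reactions$reversible)
  net <- structure(
    list(metabolites = metabolites, reactions = reactions),
    class = "metabolic_network"
  )
  validate_network(net)
  net
}

#' Validate a metabolic network
#'
#' Checks referential integrity (every metabolite cited by a reaction is
#' declared), id uniqueness, compartment labels, non-empty stoichiometries,
#' and that exchange pseudo-reactions (reactions touching a single
#' metabolite) only touch metabolites flagged as exchanged.
#'
#' @param net A \code{metabolic_network}.
#' @return \code{net}, invisibly, if valid; otherwise an error is raised.
#' @export
validate_network <- function(net) {
  m <- net$metabolites
  r <- net$reactions
  if (anyDuplicated(m$id))
    stop("duplicate metabolite ids: ",
         paste(unique(m$id[duplicated(m$id)]), collapse = ", "))
  if (anyDuplicated(r$id))
    stop("duplicate reaction ids: ",
         paste(unique(r$id[duplicated(r$id)]), collapse = ", "))
  bad_comp <- setdiff(unique(m$compartment), COMPARTMENTS)
  if (length(bad_comp))
    stop("unknown compartment tag(s): ", paste(bad_comp, collapse = ", "))
  for (i in seq_len(nrow(r))) {
    st <- r$stoichiometry[[i]]
    if (length(st) == 0L)
      stop("reaction '", r$id[i], "' has empty stoichiometry")
    unknown <- setdiff(names(st), m$id)
    if (length(unknown))
      stop("reaction '", r$id[i], "' references undefined metabolite(s): ",
           paste(unknown, collapse = ", "))
    if (length(st) == 1L) {
      ex <- m$exchanged[match(names(st), m$id)]
      if (!ex)
        stop("exchange pseudo-reaction '", r$id[i],
             "' touches internal metabolite '", names(st), "'")
    }
  }
  invisible(net)
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat("metabolic_network:", nrow(x$reactions), "reactions,",
      nrow(x$metabolites), "metabolites (",
      sum(!x$metabolites$exchanged), "internal )\n")
  cat("subsystems:",
      paste(sort(unique(x$reactions$subsystem)), collapse = ", "), "\n")
  invisible(x)
}

#' Reaction ids of irreversible reactions
#' @param net A \code{metabolic_network}.
#' @return Character vector of reaction ids with \code{reversible = FALSE}.
#' @export
irreversible_ids <- function(net) {
  net$reactions$id[!net$reactions$reversible]
}

## ---- equation strings ------------------------------------------------------

parse_equation <- function(eq, rxn_id = "?") {
  eq <- trimws(eq)
  if (grepl("<=>", eq, fixed = TRUE)) {
    sides <- strsplit(eq, "<=>", fixed = TRUE)[[1]]
  } else if (grepl("->", eq, fixed = TRUE)) {
    sides <- strsplit(eq, "->", fixed = TRUE)[[1]]
  } else {
    stop("malformed equation in reaction '", rxn_id, "': no arrow found")
  }
  if (length(sides) == 1L) sides <- c(sides, "")
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (side == "") return(numeric(0))
    terms <- trimws(strsplit(side, " + ", fixed = TRUE)[[1]])
    out <- numeric(0)
    for (tm in terms) {
      if (tm == "") next
      parts <- strsplit(tm, "[[:space:]]+")[[1]]
      if (length(parts) == 1L) {
        coef <- 1
        met <- parts
      } else if (length(parts) == 2L) {
        coef <- suppressWarnings(as.numeric(parts[1]))
        met <- parts[2]
        if (is.na(coef))
          stop("malformed stoichiometry in reaction '", rxn_id,
               "': cannot parse coefficient in term '", tm, "'")
      } else {
        stop("malformed stoichiometry in reaction '", rxn_id,
             "': term '", tm, "'")
      }
      out[met] <- (if (met %in% names(out)) out[met] else 0) + sign * coef
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  st <- lhs
  for (met in names(rhs)) st[met] <- (if (met %in% names(st)) st[met] else 0) + rhs[met]
  st <- st[st != 0]
  if (length(st) == 0L)
    stop("reaction '", rxn_id, "' has empty stoichiometry after cancellation")
  st
}

format_equation <- function(st, reversible) {
  fmt_side <- function(v) {
    if (length(v) == 0L) return("")
    paste(vapply(seq_along(v), function(i) {
      co <- v[i]
      if (co == 1) names(v)[i]
      else paste(format(co, digits = 17, scientific = FALSE), names(v)[i])
    }, character(1)), collapse = " + ")
  }
  lhs <- -st[st < 0]
  rhs <- st[st > 0]
  arrow <- if (reversible) "<=>" else "->"
  paste(fmt_side(lhs), arrow, fmt_side(rhs))
}

infer_metabolites <- function(ids) {
  comp <- rep("cytosolic", length(ids))
  comp[grepl("_e$", ids)] <- "extracellular"
  comp[grepl("_m$", ids)] <- "mitochondrial"
  data.frame(id = ids, name = ids, compartment = comp,
             exchanged = grepl("_e$", ids), stringsAsFactors = FALSE)
}

## ---- loading / saving ------------------------------------------------------

#' Load a metabolic network from file
#'
#' Tabular format: a tab-delimited reaction table with columns \code{id},
#' \code{name}, \code{equation} (e.g. \code{"2 h_m + nadh_m -> ..."} with
#' compartment suffixes \code{_e}/\code{_c}/\code{_m}), \code{reversible}
#' (0/1), \code{subsystem} and a semicolon-separated \code{genes} column.
#' Metabolite annotations (names, exchanged flags) are read from a companion
#' table; without one, compartments are inferred from id suffixes and all
#' extracellular species are treated as exchanged.  JSON format: a single
#' document holding both tables.
#'
#' @param path Path to the reaction table (tabular) or JSON document.
#' @param format \code{"tabular"} or \code{"json"}.
#' @param metabolites Optional path to the metabolite table (tabular format
#'   only).  Defaults to \code{<path>} with the extension replaced by
#'   \code{"_metabolites.tsv"} when that file exists.
#' @return A validated \code{metabolic_network}.
#' @export
load_network <- function(path, format = c("tabular", "json"),
                         metabolites = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (format == "json") {
    doc <- jsonlite::read_json(path, simplifyVector = FALSE)
    mets <- do.call(rbind, lapply(doc$metabolites, function(m)
      data.frame(id = m$id, name = m$name, compartment = m$compartment,
                 exchanged = isTRUE(m$exchanged), stringsAsFactors = FALSE)))
    rx <- data.frame(
      id = vapply(doc$reactions, `[[`, character(1), "id"),
      name = vapply(doc$reactions, `[[`, character(1), "name"),
      reversible = vapply(doc$reactions, function(r) isTRUE(r$reversible),
                          logical(1)),
      subsystem = vapply(doc$reactions, `[[`, character(1), "subsystem"),
      stringsAsFactors = FALSE)
    rx$stoichiometry <- I(lapply(doc$reactions, function(r)
      unlist(r$stoichiometry)))
    rx$genes <- I(lapply(doc$reactions, function(r)
      as.character(unlist(r$genes))))
    return(metabolic_network(mets, rx))
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, na.strings = NULL)
  required <- c("id", "equation", "reversible", "subsystem")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("model file lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (is.null(tab$name)) tab$name <- tab$id
  if (is.null(tab$genes)) tab$genes <- ""
  tab$genes[is.na(tab$genes)] <- ""
  rx <- data.frame(id = tab$id, name = tab$name,
                   reversible = as.logical(as.integer(tab$reversible)),
                   subsystem = tab$subsystem, stringsAsFactors = FALSE)
  rx$stoichiometry <- I(mapply(parse_equation, tab$equation, tab$id,
                               SIMPLIFY = FALSE, USE.NAMES = FALSE))
  rx$genes <- I(lapply(strsplit(tab$genes, ";", fixed = TRUE),
                       function(g) g[nzchar(trimws(g))]))
  met_ids <- unique(unlist(lapply(rx$stoichiometry, names)))
  if (is.null(metabolites)) {
    cand <- sub("\\.[^.]*$", "_metabolites.tsv", path)
    if (file.exists(cand)) metabolites <- cand
  }
  if (!is.null(metabolites)) {
    mets <- utils::read.delim(metabolites, stringsAsFactors = FALSE)
    mets$exchanged <- as.logical(as.integer(mets$exchanged))
    extra <- setdiff(met_ids, mets$id)
    if (length(extra))
      stop("metabolite table lacks: ", paste(extra, collapse = ", "))
  } else {
    mets <- infer_metabolites(met_ids)
  }
  metabolic_network(mets, rx)
}

#' Write a metabolic network to file
#'
#' Inverse of \code{\link{load_network}}; the tabular writer emits the
#' reaction table at \code{path} and the metabolite table alongside it
#' (extension replaced by \code{"_metabolites.tsv"}).
#'
#' @param net A \code{metabolic_network}.
#' @param path Output path.
#' @param format \code{"tabular"} or \code{"json"}.
#' @return \code{path}, invisibly.
#' @export
write_network <- function(net, path, format = c("tabular", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    doc <- list(
      metabolites = lapply(seq_len(nrow(net$metabolites)), function(i)
        as.list(net$metabolites[i, ])),
      reactions = lapply(seq_len(nrow(net$reactions)), function(i) {
        r <- net$reactions[i, ]
        list(id = r$id, name = r$name, reversible = r$reversible,
             subsystem = r$subsystem,
             stoichiometry = as.list(r$stoichiometry[[1]]),
             genes = as.list(r$genes[[1]]))
      }))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(path))
  }
  r <- net$reactions
  tab <- data.frame(
    id = r$id, name = r$name,
    equation = vapply(seq_len(nrow(r)), function(i)
      format_equation(r$stoichiometry[[i]], r$reversible[i]), character(1)),
    reversible = as.integer(r$reversible),
    subsystem = r$subsystem,
    genes = vapply(r$genes, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  mpath <- sub("\\.[^.]*$", "_metabolites.tsv", path)
  m <- net$metabolites
  m$exchanged <- as.integer(m$exchanged)
  utils::write.table(m, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The packaged brain central-metabolism model
#'
#' Returns the curated 69-reaction model of brain central carbon and energy
#' metabolism spanning glycolysis, the (lumped, 6-carbon-unit) pentose
#' phosphate pathway, the TCA cycle, oxidative phosphorylation with explicit
#' mitochondrial-matrix proton stoichiometry, the malate-aspartate and
#' glycerol-phosphate redox shuttles, the GABA shunt, the
#' glutamine-glutamate cycle with ammonium transport, pyruvate carboxylase
#' and malic enzyme, and transport/exchange of metabolites between the
#' extracellular, cytosolic and mitochondrial compartments.  Mitochondrial
#' matrix protons are balanced; cytosolic protons are deliberately not.
#' Reactions carry HGNC gene associations, including the mitochondrially
#' encoded ETC subunits (ND1-ND6, CYTB, COX1-3, ATP6/ATP8).
#'
#' @return A validated \code{metabolic_network} with exactly 69 reactions.
#' @export
default_brain_network <- function() {
  rpath <- system.file("extdata", "brain_reactions.tsv", package = PKG_NAME,
                       mustWork = TRUE)
  mpath <- system.file("extdata", "brain_metabolites.tsv", package = PKG_NAME,
                       mustWork = TRUE)
  load_network(rpath, format = "tabular", metabolites = mpath)
}

## ---- stoichiometric matrix -------------------------------------------------

#' Build the stoichiometric matrix of internal metabolites
#'
#' One row per internal (non-exchanged) metabolite, one column per reaction
#' in network order.  \code{S \%*\% v = 0} encodes the steady-state
#' requirement that production and consumption of every internal metabolite
#' cancel.
#'
#' @param net A validated \code{metabolic_network}.
#' @return A \code{stoich_matrix}: list with the numeric matrix \code{S},
#'   \code{row_index} (metabolite ids) and \code{col_index} (reaction ids).
#' @export
build_stoich_matrix <- function(net) {
  internal <- net$metabolites$id[!net$metabolites$exchanged]
  rx <- net$reactions
  S <- matrix(0, nrow = length(internal), ncol = nrow(rx),
              dimnames = list(internal, rx$id))
  for (j in seq_len(nrow(rx))) {
    st <- rx$stoichiometry[[j]]
    keep <- names(st) %in% internal
    if (any(keep)) S[names(st)[keep], j] <- st[keep]
  }
  structure(list(S = S, row_index = internal, col_index = rx$id),
            class = "stoich_matrix")
}

#' @export
print.stoich_matrix <- function(x, ...) {
  cat("stoich_matrix:", length(x$row_index), "internal metabolites x",
      length(x$col_index), "reactions;",
      sum(x$S != 0), "nonzero entries\n")
  invisible(x)
}

## ---- SBML ------------------------------------------------------------------

#' Export a network as SBML Level 3
#'
#' Writes an SBML L3V1 document with compartments, species (exchanged
#' species marked as having boundary condition), reactions with
#' reversibility flags and stoichiometries, and gene associations stored in
#' reaction notes.
#'
#' @param net A validated \code{metabolic_network}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
export_sbml <- function(net, path) {
  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    level = "3", version = "1")
  model <- xml2::xml_add_child(doc, "model", id = "brain_central_metabolism")
  comps <- xml2::xml_add_child(model, "listOfCompartments")
  comp_ids <- c(extracellular = "e", cytosolic = "c", mitochondrial = "m")
  for (cc in unique(net$metabolites$compartment))
    xml2::xml_add_child(comps, "compartment", id = comp_ids[[cc]], name = cc,
                        constant = "true")
  sps <- xml2::xml_add_child(model, "listOfSpecies")
  for (i in seq_len(nrow(net$metabolites))) {
    m <- net$metabolites[i, ]
    xml2::xml_add_child(
      sps, "species", id = paste0("M_", m$id), name = m$name,
      compartment = comp_ids[[m$compartment]],
      boundaryCondition = tolower(as.character(m$exchanged)),
      hasOnlySubstanceUnits = "false", constant = "false")
  }
  rxs <- xml2::xml_add_child(model, "listOfReactions")
  for (i in seq_len(nrow(net$reactions))) {
    r <- net$reactions[i, ]
    rn <- xml2::xml_add_child(
      rxs, "reaction", id = paste0("R_", r$id), name = r$name,
      reversible = tolower(as.character(r$reversible)), fast = "false")
    notes <- xml2::xml_add_child(rn, "notes")
    body <- xml2::xml_add_child(notes, "body",
                                xmlns = "http://www.w3.org/1999/xhtml")
    xml2::xml_add_child(body, "p",
                        paste0("SUBSYSTEM: ", r$subsystem))
    xml2::xml_add_child(body, "p",
                        paste0("GENE_ASSOCIATION: ",
                               paste(r$genes[[1]], collapse = ";")))
    st <- r$stoichiometry[[1]]
    if (any(st < 0)) {
      lr <- xml2::xml_add_child(rn, "listOfReactants")
      for (met in names(st)[st < 0])
        xml2::xml_add_child(lr, "speciesReference",
                            species = paste0("M_", met),
                            stoichiometry = format(-st[[met]], digits = 17),
                            constant = "true")
    }
    if (any(st > 0)) {
      lp <- xml2::xml_add_child(rn, "listOfProducts")
      for (met in names(st)[st > 0])
        xml2::xml_add_child(lp, "speciesReference",
                            species = paste0("M_", met),
                            stoichiometry = format(st[[met]], digits = 17),
                            constant = "true")
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Import a network from an SBML Level 3 document written by
#' \code{\link{export_sbml}}
#'
#' @param path SBML file path.
#' @return A validated \code{metabolic_network} (empty networks allowed).
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")
  comp_names <- c(e = "extracellular", c = "cytosolic", m = "mitochondrial")
  sp_nodes <- xml2::xml_find_all(doc, ".//s:species", ns)
  mets <- data.frame(
    id = sub("^M_", "", xml2::xml_attr(sp_nodes, "id")),
    name = xml2::xml_attr(sp_nodes, "name"),
    compartment = unname(comp_names[xml2::xml_attr(sp_nodes, "compartment")]),
    exchanged = xml2::xml_attr(sp_nodes, "boundaryCondition") == "true",
    stringsAsFactors = FALSE)
  rx_nodes <- xml2::xml_find_all(doc, ".//s:reaction", ns)
  parse_refs <- function(node, xpath, sign) {
    refs <- xml2::xml_find_all(node, xpath, ns)
    st <- sign * as.numeric(xml2::xml_attr(refs, "stoichiometry"))
    names(st) <- sub("^M_", "", xml2::xml_attr(refs, "species"))
    st
  }
  rx <- data.frame(
    id = sub("^R_", "", xml2::xml_attr(rx_nodes, "id")),
    name = xml2::xml_attr(rx_nodes, "name"),
    reversible = xml2::xml_attr(rx_nodes, "reversible") == "true",
    subsystem = rep(NA_character_, length(rx_nodes)),
    stringsAsFactors = FALSE)
  stoich <- vector("list", length(rx_nodes))
  genes <- vector("list", length(rx_nodes))
  for (i in seq_along(rx_nodes)) {
    node <- rx_nodes[[i]]
    st <- c(parse_refs(node, ".//s:listOfReactants/s:speciesReference", -1),
            parse_refs(node, ".//s:listOfProducts/s:speciesReference", +1))
    stoich[[i]] <- st
    notes <- xml2::xml_text(xml2::xml_find_all(node, ".//s:notes//*", ns))
    sub_line <- grep("^SUBSYSTEM: ", notes, value = TRUE)
    if (length(sub_line))
      rx$subsystem[i] <- sub("^SUBSYSTEM: ", "", sub_line[1])
    g_line <- grep("^GENE_ASSOCIATION: ", notes, value = TRUE)
    genes[[i]] <- if (length(g_line)) {
      g <- strsplit(sub("^GENE_ASSOCIATION: ", "", g_line[1]), ";")[[1]]
      g[nzchar(g)]
    } else character(0)
  }
  rx$stoichiometry <- I(stoich)
  rx$genes <- I(genes)
  if (nrow(rx) == 0L && nrow(mets) == 0L)
    return(structure(list(metabolites = mets, reactions = rx),
                     class = "metabolic_network"))
  metabolic_network(mets, rx)
}
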