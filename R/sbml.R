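#' Import an SBML model (minimal level-2/3 reader)
#'
#' Reads species, global parameters and reactions (reactants, products,
#' stoichiometries, and kinetic laws written in a small MathML subset:
#' `ci`, `cn`, and `apply` with `plus`, `minus`, `times`, `divide`,
#' `power`) into a [parametric_model()].  SBML has no notion of reducible
#' parameters or projection values, so those still come from a native
#' config: the multiplicative kinetic constant of each reaction must be
#' supplied (or is guessed as the first global parameter appearing in the
#' kinetic law).
#'
#' @param path path to the SBML file.
#' @param multiplicative optional character vector naming the
#'   multiplicative constant of each reaction, in document order.
#' @return a list with `model` and the raw `species`/`parameters` tables.
#' @export
read_sbml_model <- function(path, multiplicative = NULL) {
  if (!file.exists(path)) stop(sprintf("SBML file '%s' does not exist", path), call. = FALSE)
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")

  sp_nodes <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  if (length(sp_nodes) == 0L) stop("SBML: no species found", call. = FALSE)
  species <- data.frame(
    id = xml2::xml_attr(sp_nodes, "id"),
    initial = as.numeric(ifelse(is.na(xml2::xml_attr(sp_nodes, "initialConcentration")),
                                xml2::xml_attr(sp_nodes, "initialAmount"),
                                xml2::xml_attr(sp_nodes, "initialConcentration"))),
    stringsAsFactors = FALSE)
  species$initial[is.na(species$initial)] <- 0

  par_nodes <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  parameters <- data.frame(
    id = xml2::xml_attr(par_nodes, "id"),
    value = as.numeric(xml2::xml_attr(par_nodes, "value")),
    stringsAsFactors = FALSE)

  rx_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (length(rx_nodes) == 0L) stop("SBML: no reactions found", call. = FALSE)

  reactions <- lapply(seq_along(rx_nodes), function(j) {
    rx <- rx_nodes[[j]]
    get_refs <- function(xp) {
      nodes <- xml2::xml_find_all(rx, xp, ns)
      if (length(nodes) == 0L) return(NULL)
      st <- as.numeric(xml2::xml_attr(nodes, "stoichiometry"))
      st[is.na(st)] <- 1
      stats::setNames(st, xml2::xml_attr(nodes, "species"))
    }
    reac <- get_refs(".//s:listOfReactants/s:speciesReference")
    prod <- get_refs(".//s:listOfProducts/s:speciesReference")
    st <- numeric(0)
    at <- function(s) if (s %in% names(st)) st[[s]] else 0
    if (!is.null(reac)) for (s in names(reac)) st[s] <- at(s) - reac[[s]]
    if (!is.null(prod)) for (s in names(prod)) st[s] <- at(s) + prod[[s]]
    st <- st[st != 0]
    math <- xml2::xml_find_first(rx, ".//s:kineticLaw//*[local-name()='math']/*", ns)
    rate <- tf_mathml_to_string(math)
    list(stoichiometry = st, rate = rate, j = j)
  })

  rate_constants <- multiplicative
  if (is.null(rate_constants)) {
    rate_constants <- vapply(reactions, function(r) {
      toks <- unlist(strsplit(gsub("[^A-Za-z0-9_.]", " ", r$rate), "\\s+"))
      hit <- toks[toks %in% parameters$id]
      if (length(hit) == 0L) {
        stop(sprintf("SBML reaction %d: no global parameter in kinetic law; supply 'multiplicative'",
                     r$j), call. = FALSE)
      }
      hit[[1L]]
    }, "")
  }
  reactions <- lapply(seq_along(reactions), function(j) {
    r <- reactions[[j]]
    list(stoichiometry = r$stoichiometry, rate = r$rate,
         constant = rate_constants[[j]])
  })

  model <- parametric_model(species$id,
                            stats::setNames(species$initial, species$id),
                            parameters$id, reactions)
  list(model = model, species = species, parameters = parameters)
}

# Convert a MathML subtree to a restricted-grammar expression string.
tf_mathml_to_string <- function(node) {
  if (is.na(node) || length(node) == 0L) stop("SBML: missing kinetic law math", call. = FALSE)
  tag <- xml2::xml_name(node)
  if (tag == "ci") return(trimws(xml2::xml_text(node)))
  if (tag == "cn") return(trimws(xml2::xml_text(node)))
  if (tag == "apply") {
    children <- xml2::xml_children(node)
    op <- xml2::xml_name(children[[1L]])
    args <- vapply(children[-1L], tf_mathml_to_string, "")
    sym <- switch(op, plus = "+", minus = "-", times = "*", divide = "/",
                  power = "^",
                  stop(sprintf("SBML: unsupported MathML operator '%s'", op),
                       call. = FALSE))
    if (op == "minus" && length(args) == 1L) return(paste0("(-", args, ")"))
    return(paste0("(", paste(args, collapse = paste0(" ", sym, " ")), ")"))
  }
  stop(sprintf("SBML: unsupported MathML element '%s'", tag), call. = FALSE)
}
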