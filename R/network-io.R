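#' Read a reaction network from the native text format or SBML
#'
#' The native format is line oriented and whitespace-insensitive. `#` starts a
#' comment. Species are declared in one or more header lines
#' `species: A=100, B=50`; each reaction occupies one line
#' `R1: A + B -> C + 0 @ 2.0`, where either side may list one or two terms and
#' `0` names the omnipresent placeholder. Parse errors carry the offending
#' line number; semantic violations (more than two reactants/products,
#' undeclared species, non-positive rates) are collected via
#' [validate_network()] and reported together.
#'
#' @param con a file path, or a character vector of lines (native format
#'   only).
#' @param format `"native"` or `"sbml"`.
#' @param self_half passed to [reaction_system()].
#' @return a `reaction_system`.
#' @seealso [write_network()] for the inverse; round-tripping a system through
#'   write/read reproduces it exactly.
#' @export
read_network <- function(con, format = c("native", "sbml"), self_half = TRUE) {
  format <- match.arg(format)
  if (format == "sbml") return(read_sbml(con, self_half = self_half))
  lines <- if (length(con) == 1L && file.exists(con)) readLines(con) else con
  lines <- sub("#.*$", "", lines)
  sp_ids <- character(0)
  sp_counts <- numeric(0)
  rx <- list()
  for (ln in seq_along(lines)) {
    s <- trimws(lines[ln])
    if (s == "") next
    if (grepl("^species\\s*:", s)) {
      body <- sub("^species\\s*:", "", s)
      pairs <- trimws(strsplit(body, ",", fixed = TRUE)[[1]])
      pairs <- pairs[pairs != ""]
      for (p in pairs) {
        kv <- trimws(strsplit(p, "=", fixed = TRUE)[[1]])
        if (length(kv) != 2L || kv[1] == "")
          stop(sprintf("parse error at line %d: expected id=count, got \"%s\"", ln, p))
        cnt <- suppressWarnings(as.numeric(kv[2]))
        if (is.na(cnt))
          stop(sprintf("parse error at line %d: bad count in \"%s\"", ln, p))
        sp_ids <- c(sp_ids, kv[1])
        sp_counts <- c(sp_counts, cnt)
      }
      next
    }
    m <- regmatches(s, regexec(
      "^([^:]+):(.*)->(.*)@(.*)$", s))[[1]]
    if (length(m) != 5L)
      stop(sprintf("parse error at line %d: not a reaction line: \"%s\"", ln, s))
    id <- trimws(m[2])
    lhs <- trimws(strsplit(m[3], "+", fixed = TRUE)[[1]])
    rhs <- trimws(strsplit(m[4], "+", fixed = TRUE)[[1]])
    if (id == "" || any(lhs == "") || any(rhs == "") ||
        length(lhs) == 0L || length(rhs) == 0L)
      stop(sprintf("parse error at line %d: empty term in \"%s\"", ln, s))
    rate_s <- trimws(m[5])
    rx[[length(rx) + 1L]] <- list(id = id, line = ln,
                                  reactants = paste(lhs, collapse = " + "),
                                  products = paste(rhs, collapse = " + "),
                                  rate = rate_s)
  }
  rxdf <- if (length(rx)) {
    data.frame(id = vapply(rx, `[[`, "", "id"),
               reactants = vapply(rx, `[[`, "", "reactants"),
               products = vapply(rx, `[[`, "", "products"),
               rate = vapply(rx, `[[`, "", "rate"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(id = character(0), reactants = character(0),
               products = character(0), rate = character(0))
  }
  spdf <- data.frame(id = sp_ids, count = sp_counts, stringsAsFactors = FALSE)
  report <- validate_network(spdf, rxdf)
  if (nrow(report))
    stop("invalid network:\n", paste(sprintf("  %s: %s", report$where,
                                             report$problem), collapse = "\n"))
  pad2 <- function(terms) {
    t <- trimws(strsplit(terms, "+", fixed = TRUE)[[1]])
    t <- t[t != ""]
    t[t == "0"] <- NA
    c(t, NA, NA)[1:2]
  }
  if (nrow(rxdf)) {
    rmat <- t(vapply(rxdf$reactants, pad2, character(2)))
    pmat <- t(vapply(rxdf$products, pad2, character(2)))
    reactions <- data.frame(id = rxdf$id, r1 = rmat[, 1], r2 = rmat[, 2],
                            p1 = pmat[, 1], p2 = pmat[, 2],
                            rate = as.numeric(rxdf$rate),
                            stringsAsFactors = FALSE)
  } else {
    reactions <- data.frame(id = character(0), r1 = character(0),
                            r2 = character(0), p1 = character(0),
                            p2 = character(0), rate = numeric(0))
  }
  reaction_system(spdf, reactions, self_half = self_half)
}

#' Serialize a reaction system to the native text format
#'
#' Writes the canonical form: one `species:` header, then one line per
#' reaction with both slots explicit (`0` for the placeholder) and rates
#' printed with full precision, so `read_network(write_network(sys))`
#' reproduces `sys` exactly.
#'
#' @param system a `reaction_system`.
#' @param path optional file path; if omitted the lines are returned.
#' @return character vector of lines (invisibly when `path` is given).
#' @export
write_network <- function(system, path = NULL) {
  sp <- system$species
  rx <- system$reactions
  head <- paste0("species: ",
                 paste(sprintf("%s=%s", sp$id[-1L],
                               format(sp$count[-1L], scientific = FALSE)),
                       collapse = ", "))
  nm <- function(i) sp$id[i]
  body <- sprintf("%s: %s + %s -> %s + %s @ %s",
                  rx$id, nm(rx$r1), nm(rx$r2), nm(rx$p1), nm(rx$p2),
                  formatC(rx$rate, digits = 17, format = "g"))
  out <- c(head, body)
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Ingest a restricted mass-action SBML model
#'
#' Supports SBML Level 2/3 documents whose reactions are irreversible, have at
#' most two reactant and two product units (counting stoichiometry), and whose
#' kinetic law is a plain mass-action product: either a bare constant, or
#' `<apply><times> ... </apply>` over exactly one rate constant (a local or
#' global parameter, or a numeric literal) and the reactant species. Initial
#' amounts must be non-negative integers. Anything else raises an
#' unsupported-kinetics error; this ingest path is deliberately narrow.
#'
#' @param path path to an SBML file.
#' @param self_half passed to [reaction_system()].
#' @return a `reaction_system`.
#' @export
read_sbml <- function(path, self_half = TRUE) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (length(sp_nodes) == 0L) stop("SBML: no species found")
  sid <- xml2::xml_attr(sp_nodes, "id")
  amt <- suppressWarnings(as.numeric(xml2::xml_attr(sp_nodes, "initialAmount")))
  amt[is.na(amt)] <- 0
  gp_nodes <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  gpar <- stats::setNames(
    suppressWarnings(as.numeric(xml2::xml_attr(gp_nodes, "value"))),
    xml2::xml_attr(gp_nodes, "id"))

  expand_sr <- function(node, what) {
    refs <- xml2::xml_find_all(node, sprintf(".//%s/speciesReference", what))
    out <- character(0)
    for (ref in refs) {
      s <- xml2::xml_attr(ref, "species")
      st <- xml2::xml_attr(ref, "stoichiometry")
      st <- if (is.na(st)) 1 else as.numeric(st)
      if (is.na(st) || st != floor(st) || st < 1)
        stop("SBML: non-integer stoichiometry in reaction ",
             xml2::xml_attr(node, "id"))
      out <- c(out, rep(s, st))
    }
    out
  }

  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rows <- list()
  for (node in rx_nodes) {
    rid <- xml2::xml_attr(node, "id")
    rev <- xml2::xml_attr(node, "reversible")
    if (identical(rev, "true"))
      stop("SBML: reversible reactions are not supported (reaction ", rid,
           "); split into two irreversible reactions")
    reac <- expand_sr(node, "listOfReactants")
    prod <- expand_sr(node, "listOfProducts")
    if (length(reac) > 2L || length(prod) > 2L)
      stop("SBML: reaction ", rid, " has more than two reactants or products")
    kl <- xml2::xml_find_first(node, ".//kineticLaw")
    if (inherits(kl, "xml_missing"))
      stop("SBML: reaction ", rid, " has no kinetic law")
    lpar_nodes <- xml2::xml_find_all(
      kl, ".//listOfLocalParameters/localParameter | .//listOfParameters/parameter")
    lpar <- stats::setNames(
      suppressWarnings(as.numeric(xml2::xml_attr(lpar_nodes, "value"))),
      xml2::xml_attr(lpar_nodes, "id"))
    params <- c(lpar, gpar[setdiff(names(gpar), names(lpar))])
    rate <- parse_mass_action_math(kl, rid, reac, params)
    rows[[length(rows) + 1L]] <- data.frame(
      id = rid,
      r1 = if (length(reac) >= 1L) reac[1] else NA,
      r2 = if (length(reac) >= 2L) reac[2] else NA,
      p1 = if (length(prod) >= 1L) prod[1] else NA,
      p2 = if (length(prod) >= 2L) prod[2] else NA,
      rate = rate, stringsAsFactors = FALSE)
  }
  reaction_system(
    data.frame(id = sid, count = amt, stringsAsFactors = FALSE),
    do.call(rbind, rows), self_half = self_half)
}

# Extract the rate constant from a kinetic law restricted to mass action:
# the MathML must be a lone <ci>/<cn>, or <apply><times> over one constant and
# the reactant species (multiset match).
parse_mass_action_math <- function(kl, rid, reactants, params) {
  math <- xml2::xml_find_first(kl, ".//math")
  if (inherits(math, "xml_missing"))
    stop("SBML: reaction ", rid, " kinetic law has no <math>")
  kids <- xml2::xml_children(math)
  if (length(kids) != 1L)
    stop("SBML: unsupported kinetics in reaction ", rid)
  top <- kids[[1]]
  leaf_value <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "cn") return(as.numeric(xml2::xml_text(node)))
    if (nm == "ci") {
      ref <- trimws(xml2::xml_text(node))
      if (ref %in% names(params)) return(params[[ref]])
      return(ref)  # species symbol
    }
    stop("SBML: unsupported kinetics in reaction ", rid)
  }
  if (xml2::xml_name(top) %in% c("ci", "cn")) {
    v <- leaf_value(top)
    if (!is.numeric(v) || length(reactants) != 0L)
      stop("SBML: unsupported kinetics in reaction ", rid,
           " (expected mass action)")
    return(v)
  }
  if (xml2::xml_name(top) != "apply")
    stop("SBML: unsupported kinetics in reaction ", rid)
  terms <- xml2::xml_children(top)
  if (length(terms) < 2L || xml2::xml_name(terms[[1]]) != "times")
    stop("SBML: unsupported kinetics in reaction ", rid,
         " (only k * reactants mass action is accepted)")
  vals <- lapply(terms[-1], leaf_value)
  consts <- vapply(vals, is.numeric, logical(1))
  if (sum(consts) != 1L)
    stop("SBML: unsupported kinetics in reaction ", rid,
         " (exactly one rate constant expected)")
  symbols <- unlist(vals[!consts])
  if (!identical(sort(symbols), sort(reactants)))
    stop("SBML: unsupported kinetics in reaction ", rid,
         " (kinetic law is not mass action over the reactants)")
  vals[consts][[1]]
}
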