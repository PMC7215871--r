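#' Define a domain as a union of residue-number ranges
#'
#' Residue numbering is 1-based and ranges are inclusive, so
#' `domain_definition("NTD", list(c(30, 250)))` selects residues 30..250.
#' Intervals are sorted and must not overlap within one definition;
#' different domains may overlap each other (e.g. cytosolic loops carved out
#' of a transmembrane range), which is permitted by design.
#'
#' @param name domain name
#' @param ranges list of length-2 integer vectors `c(start, end)`, or a
#'   character vector of `"start-end"` strings
#' @param chain_id optional chain restriction; `NULL` selects the system's
#'   first chain
#' @return an object of class `domain_definition`
#' @export
domain_definition <- function(name, ranges, chain_id = NULL) {
  if (is.character(ranges)) ranges <- lapply(ranges, parse_range_string)
  if (is.numeric(ranges) && length(ranges) == 2L) ranges <- list(ranges)
  rng <- do.call(rbind, lapply(ranges, function(r) {
    if (length(r) != 2L || any(is.na(r)) || r[1] > r[2])
      stop("invalid residue range in domain '", name, "': ",
           paste(r, collapse = "-"))
    as.integer(r)
  }))
  rng <- rng[order(rng[, 1]), , drop = FALSE]
  if (nrow(rng) > 1L && any(rng[-1, 1] <= rng[-nrow(rng), 2]))
    stop("overlapping residue ranges within domain '", name, "'")
  structure(list(name = name, ranges = rng, chain_id = chain_id),
            class = "domain_definition")
}

parse_range_string <- function(s) {
  m <- regmatches(s, regexec("^\\s*(\\d+)\\s*-\\s*(\\d+)\\s*$", s))[[1]]
  if (length(m) != 3L) stop("cannot parse residue range string: '", s, "'")
  as.integer(m[2:3])
}

#' @export
print.domain_definition <- function(x, ...) {
  cat(sprintf("domain %s: residues %s%s\n", x$name,
              paste(apply(x$ranges, 1, paste, collapse = "-"), collapse = ","),
              if (is.null(x$chain_id)) "" else paste0(" (chain ", x$chain_id, ")")))
  invisible(x)
}

#' Default NPC1 domain partition
#'
#' The six-domain partition used for inter-domain correlation analysis of
#' NPC1 (1278 residues): NTD 30-250, MLD 374-620, CTD 861-1083, the
#' transmembrane helices as the union 260-373 / 621-797 / 1084-1278, the
#' NTD-TM linker 251-259, and the cytosolic loops 290-337. Published domain
#' boundaries for NPC1 vary by a few residues between structural depictions
#' (e.g. NTD is sometimes drawn as 25-264 and CTD as 854-1083); the defaults
#' here follow the boundaries used for the correlation tables. Note the
#' cytosolic-loop range lies inside the first transmembrane range: domains
#' in this partition may overlap.
#'
#' @return named list of [domain_definition()] objects
#' @export
npc1_domains <- function() {
  list(
    NTD      = domain_definition("NTD",      list(c(30, 250))),
    MLD      = domain_definition("MLD",      list(c(374, 620))),
    CTD      = domain_definition("CTD",      list(c(861, 1083))),
    TMD      = domain_definition("TMD",      list(c(260, 373), c(621, 797), c(1084, 1278))),
    Linker   = domain_definition("Linker",   list(c(251, 259))),
    CytLoops = domain_definition("CytLoops", list(c(290, 337)))
  )
}

#' Read domain definitions from a YAML config
#'
#' Expected layout: a top-level `domains` mapping (or the whole document)
#' from domain name to a list of `"start-end"` strings, e.g.
#' \preformatted{
#' domains:
#'   NTD: ["30-250"]
#'   TMD: ["260-373", "621-797", "1084-1278"]
#' }
#'
#' @param path YAML file path
#' @return named list of [domain_definition()] objects
#' @export
read_domain_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$domains)) cfg <- cfg$domains
  if (!length(cfg)) stop("no domain definitions found in ", path)
  out <- lapply(names(cfg), function(nm) {
    entry <- cfg[[nm]]
    if (is.list(entry) && !is.null(entry$ranges))
      domain_definition(nm, entry$ranges, chain_id = entry$chain_id)
    else
      domain_definition(nm, entry)
  })
  stats::setNames(out, names(cfg))
}

#' Construct an atom selection
#'
#' @param indices sorted unique 1-based indices into the system's atom order
#' @param provenance human-readable description, e.g. `"NTD backbone"`
#' @return object of class `atom_selection`
#' @export
atom_selection <- function(indices, provenance = "") {
  indices <- as.integer(indices)
  if (is.unsorted(indices, strictly = TRUE))
    indices <- sort(unique(indices))
  structure(indices, provenance = provenance, class = "atom_selection")
}

#' @export
print.atom_selection <- function(x, ...) {
  cat(sprintf("atom_selection '%s': %d atoms\n",
              attr(x, "provenance"), length(x)))
  invisible(x)
}

#' Resolve a domain definition to atom indices
#'
#' @param system a [molecular_system()]
#' @param domain a [domain_definition()], or `NULL` for the whole system
#' @param atom_filter `"backbone"` (atom names N/CA/C/O of standard amino
#'   acids), `"heavy"` (everything but hydrogen), `"all"`, or a character
#'   vector of atom names to keep
#' @return an [atom_selection()]; errors if the selection is empty
#' @export
resolve_selection <- function(system, domain = NULL, atom_filter = "backbone") {
  a <- system$atoms
  keep <- rep(TRUE, nrow(a))
  label <- "all atoms"

  if (!is.null(domain)) {
    if (!inherits(domain, "domain_definition"))
      stop("domain must be a domain_definition")
    chain <- domain$chain_id
    if (is.null(chain)) chain <- a$chain_id[1]
    in_range <- rep(FALSE, nrow(a))
    for (k in seq_len(nrow(domain$ranges)))
      in_range <- in_range | (a$residue_number >= domain$ranges[k, 1] &
                              a$residue_number <= domain$ranges[k, 2])
    keep <- keep & in_range & a$chain_id == chain
    label <- domain$name
  }

  if (length(atom_filter) == 1L && atom_filter %in% c("backbone", "heavy", "all")) {
    keep <- switch(atom_filter,
      backbone = keep & a$atom_name %in% c("N", "CA", "C", "O") &
                 a$residue_name %in% STANDARD_RESIDUES,
      heavy = keep & !(a$element %in% c("H", "D")),
      all = keep)
    label <- paste(label, atom_filter)
  } else {
    keep <- keep & a$atom_name %in% atom_filter
    label <- paste(label, "names:", paste(atom_filter, collapse = ","))
  }

  idx <- which(keep)
  if (!length(idx))
    stop("empty selection for domain '",
         if (is.null(domain)) "(whole system)" else domain$name,
         "' with filter '", paste(atom_filter, collapse = ","), "'")
  atom_selection(idx, provenance = label)
}

#' Locate a single atom by residue number and atom name
#'
#' @param system a [molecular_system()]
#' @param residue_number residue number
#' @param atom_name atom name (e.g. `"CA"`, `"OG"`, `"C25"`)
#' @param chain_id optional chain; defaults to the first chain
#' @return 1-based atom index (length-1 integer)
#' @export
find_atom <- function(system, residue_number, atom_name, chain_id = NULL) {
  a <- system$atoms
  if (is.null(chain_id)) chain_id <- a$chain_id[1]
  hit <- which(a$residue_number == residue_number &
               a$atom_name == atom_name &
               a$chain_id == chain_id)
  if (length(hit) == 1L) return(hit)
  if (length(hit) > 1L)
    stop("ambiguous atom: ", length(hit), " atoms match ",
         chain_id, "/", residue_number, "/", atom_name)
  near <- a$atom_name[a$residue_number == residue_number & a$chain_id == chain_id]
  stop("no atom '", atom_name, "' in residue ", residue_number,
       " (chain ", chain_id, ")",
       if (length(near)) paste0("; atoms present: ",
                                paste(unique(near), collapse = ", "))
       else "; residue not present in system")
}
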