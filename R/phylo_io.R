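#' Read a rooted time-calibrated tree
#'
#' Reads a chronogram whose branch lengths are durations in Myr. The tree must
#' be rooted and every non-root edge must carry a branch length. Internal
#' edges shorter than `DEGEN_EPS` (1e-8 Myr) are collapsed into polytomies;
#' pendant (tip) edges are exempt from collapsing so that very young tips are
#' never silently deleted.
#'
#' @param path file path.
#' @param format `"newick"` or `"nexus"` (TREES block, translate tables
#'   resolved by \pkg{ape}).
#' @return an object of class `phylo` with durations in Myr.
#' @seealso [tip_ages()], [prune_fossil_tips()], [graft_outgroup()]
#' @export
read_time_tree <- function(path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  tree <- switch(format,
    newick = ape::read.tree(path),
    nexus  = ape::read.nexus(path)
  )
  if (inherits(tree, "multiPhylo")) {
    if (length(tree) != 1L)
      stop("file contains ", length(tree), " trees; expected exactly one")
    tree <- tree[[1L]]
  }
  if (is.null(tree)) stop("could not parse tree file: ", path)
  validate_time_tree(tree)
}

#' Validate and normalise a chronogram
#'
#' Checks rootedness, branch-length presence and positivity, and duplicate tip
#' labels, then collapses degenerate internal edges (`< DEGEN_EPS` Myr) into
#' polytomies.
#'
#' @param tree a `phylo` object.
#' @return the validated (possibly collapsed) `phylo` object.
#' @export
validate_time_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (is.null(tree$edge.length)) {
    bad <- paste(tree$edge[1, ], collapse = "->")
    stop("tree has no branch lengths (first edge ", bad, "); a chronogram is required")
  }
  if (length(tree$edge.length) != nrow(tree$edge)) {
    missing_e <- which(is.na(tree$edge.length))[1]
    stop("missing branch length on edge ",
         paste(tree$edge[missing_e, ], collapse = "->"))
  }
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0)) {
    bad <- which(is.na(tree$edge.length) | tree$edge.length < 0)[1]
    stop("negative or missing duration on edge ",
         paste(tree$edge[bad, ], collapse = "->"))
  }
  if (!ape::is.rooted(tree))
    stop("tree is unrooted; root it (e.g. ape::root()) before analysis")
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate tip labels: ", paste(dup, collapse = ", "))
  }
  ape::di2multi(tree, tol = DEGEN_EPS)
}

#' Write a chronogram
#'
#' @param tree a `phylo` object.
#' @param path output file path.
#' @param format `"newick"` or `"nexus"`.
#' @export
write_time_tree <- function(tree, path, format = c("newick", "nexus")) {
  format <- match.arg(format)
  switch(format,
    newick = ape::write.tree(tree, file = path),
    nexus  = ape::write.nexus(tree, file = path, translate = TRUE)
  )
  invisible(path)
}

#' Node and tip ages of a chronogram
#'
#' Ages are in Myr before present, with the present defined by the deepest
#' root-to-tip path (extant tips sit at age 0 up to float noise).
#'
#' @param tree a `phylo` object with durations.
#' @return `tip_ages()`: named numeric vector over tips. `node_ages()`: numeric
#'   vector over all node indices (tips then internals, `ape` order).
#'   `root_age()`: scalar age of the root.
#' @export
tip_ages <- function(tree) {
  a <- node_ages(tree)[seq_len(ape::Ntip(tree))]
  names(a) <- tree$tip.label
  a
}

#' @rdname tip_ages
#' @export
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth[seq_len(ape::Ntip(tree))]) - depth
}

#' @rdname tip_ages
#' @export
root_age <- function(tree) {
  unname(node_ages(tree)[ape::Ntip(tree) + 1L])
}

#' Which tips are fossils?
#'
#' A tip is a fossil iff its age before present exceeds `AGE_EPS` (1e-3 Myr).
#'
#' @param tree a `phylo` object.
#' @return named logical vector over tips.
#' @export
is_fossil_tip <- function(tree) {
  tip_ages(tree) > AGE_EPS
}

#' Remove fossil tips from a chronogram
#'
#' Drops every tip older than `AGE_EPS`, suppressing the resulting degree-2
#' nodes (their durations are summed), so that root-to-tip path lengths of the
#' retained extant tips are unchanged.
#'
#' @param tree a `phylo` object.
#' @return the extant-only `phylo` object.
#' @export
prune_fossil_tips <- function(tree) {
  fos <- is_fossil_tip(tree)
  if (!any(fos)) return(tree)
  if (sum(!fos) < 3L)
    stop("pruning fossils would leave ", sum(!fos), " tips; need at least 3")
  ape::drop.tip(tree, which(fos))
}

#' Graft a pseudo-outgroup tip of known mass
#'
#' Encodes prior knowledge of the ancestral mass by adding an artificial dated
#' outgroup tip near the root: a new root is created whose two children are
#' the original crown root and a short pendant tip carrying `outgroup_mass`.
#' Under the default `mode = "total"`, the outgroup tip is separated from the
#' crown by `separation` Myr in total path length (stem = separation − pendant,
#' the default 4.99 + 0.01 = 5 Myr); under `mode = "stem"` the stem edge itself
#' is `separation` Myr long. The grafted tip has a positive age
#' (new root age − pendant), i.e. it is a fossil tip.
#'
#' @param tree crown-clade chronogram (`phylo`).
#' @param traits a `trait_table` covering the tree's tips.
#' @param outgroup_mass mass in kg assigned to the pseudo-outgroup.
#' @param separation Myr separating the outgroup from the crown (default 5).
#' @param pendant Myr of the edge leading to the outgroup tip (default 0.01).
#' @param mode `"total"`: `separation` is tip-to-crown path length;
#'   `"stem"`: `separation` is the stem-edge length.
#' @param label tip label for the grafted outgroup.
#' @return a list with elements `tree`, `traits`, `crown_node` (index of the
#'   original root in the new tree) and `outgroup_tip` (index of the new tip).
#' @export
graft_outgroup <- function(tree, traits, outgroup_mass,
                           separation = 5, pendant = 0.01,
                           mode = c("total", "stem"),
                           label = "pseudo_outgroup") {
  mode <- match.arg(mode)
  if (!is.numeric(outgroup_mass) || length(outgroup_mass) != 1L ||
      outgroup_mass <= 0)
    stop("outgroup_mass must be a single positive mass in kg")
  stem <- switch(mode, total = separation - pendant, stem = separation)
  if (stem <= 0)
    stop("separation must exceed the pendant edge (stem length ", stem, " <= 0)")
  if (pendant <= 0) stop("pendant edge length must be positive")
  if (label %in% tree$tip.label)
    stop("tip label ", label, " already present")

  n <- ape::Ntip(tree)
  m <- tree$Nnode
  # renumber: tips keep 1..n, new tip n+1, new root n+2, old internal j -> j+2
  map <- function(v) ifelse(v > n, v + 2L, v)
  edge <- cbind(map(tree$edge[, 1]), map(tree$edge[, 2]))
  edge <- rbind(c(n + 2L, n + 3L),   # new root -> old root (stem)
                c(n + 2L, n + 1L),   # new root -> outgroup tip (pendant)
                edge)
  elen <- c(stem, pendant, tree$edge.length)
  out <- list(edge = edge, edge.length = elen,
              tip.label = c(tree$tip.label, label),
              Nnode = m + 1L)
  if (!is.null(tree$node.label)) out$node.label <- c("", tree$node.label)
  class(out) <- "phylo"
  out <- ape::reorder.phylo(out, "cladewise")

  traits2 <- rbind(as.data.frame(traits),
                   data.frame(species = label, mass_kg = outgroup_mass,
                              logmass = log10(outgroup_mass)))
  class(traits2) <- c("trait_table", "data.frame")
  list(tree = out, traits = traits2,
       crown_node = n + 3L, outgroup_tip = n + 1L)
}

#' Read a species body-mass table
#'
#' Two-column delimited text (comma or tab, header optional) giving species
#' label and body mass in kg. The working scale is log10 kg: a 0.1 kg species
#' has working value -1.
#'
#' @param path file path.
#' @return a `trait_table` data frame with columns `species`, `mass_kg`,
#'   `logmass`.
#' @export
read_traits <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  has_header <- {
    fields <- strsplit(first, if (sep == "") "[[:space:]]+" else sep)[[1]]
    length(fields) >= 2L && is.na(suppressWarnings(as.numeric(fields[2])))
  }
  df <- utils::read.table(path, sep = sep, header = has_header,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  if (ncol(df) < 2L) stop("trait table must have two columns: species, mass_kg")
  species <- as.character(df[[1]])
  mass <- suppressWarnings(as.numeric(df[[2]]))
  bad <- which(is.na(mass) | mass <= 0)
  if (length(bad))
    stop("non-positive or non-numeric mass at row ", bad[1],
         " (", species[bad[1]], ")")
  trait_table(stats::setNames(mass, species))
}

#' Construct a trait table from a named mass vector
#'
#' @param mass_kg named numeric vector of body masses in kg (names = species).
#' @return a `trait_table` data frame.
#' @export
trait_table <- function(mass_kg) {
  if (is.null(names(mass_kg)) || any(!nzchar(names(mass_kg))))
    stop("mass_kg must be named by species")
  if (anyDuplicated(names(mass_kg)))
    stop("duplicate species: ",
         paste(unique(names(mass_kg)[duplicated(names(mass_kg))]), collapse = ", "))
  if (any(!is.finite(mass_kg)) || any(mass_kg <= 0))
    stop("masses must be finite and strictly positive (kg)")
  out <- data.frame(species = names(mass_kg), mass_kg = unname(mass_kg),
                    logmass = log10(unname(mass_kg)),
                    stringsAsFactors = FALSE)
  class(out) <- c("trait_table", "data.frame")
  out
}

#' Back-transform a log10-kg value to kg
#'
#' @param x numeric, log10 kg.
#' @return mass in kg.
#' @export
back_transform <- function(x) 10^x

#' Bind a trait table to a tree
#'
#' Returns tip working values (log10 kg) in tip-index order. Every tip must
#' have exactly one record; extra trait rows are allowed and ignored.
#'
#' @param tree a `phylo` object.
#' @param traits a `trait_table`.
#' @return numeric vector of length `Ntip(tree)` of log10 masses.
#' @export
bind_traits <- function(tree, traits) {
  stopifnot(inherits(traits, "data.frame"))
  idx <- match(tree$tip.label, traits$species)
  if (anyNA(idx))
    stop("tips without trait records: ",
         paste(tree$tip.label[is.na(idx)], collapse = ", "))
  stats::setNames(traits$logmass[idx], tree$tip.label)
}
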