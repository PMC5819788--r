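# Karyotype character mapping on the genus phylogeny: newick I/O via ape,
# Fitch small parsimony implemented here (per-node candidate state sets are
# needed downstream, which library parsimony scores do not expose).

#' Read / write a newick tree
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()] that turn
#' parse failures into errors and keep round-trips byte-stable.
#'
#' @param text newick string (or `file` to read from).
#' @param file optional file path.
#' @return `read_newick()` returns an [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  tr <- tryCatch(
    if (!is.null(file)) ape::read.tree(file) else ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(tr) || !inherits(tr, "phylo")) {
    src <- if (!is.null(file)) file else text
    stop(sprintf("newick parse failure near '%s'",
                 substr(paste(src, collapse = ""), 1, 60)))
  }
  tr
}

#' @rdname read_newick
#' @param tree a `phylo` object.
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(file)) ape::write.tree(tree) else ape::write.tree(tree, file = file)
}

#' The packaged Phalaris species tree
#'
#' Topology of the eight study species, transcribed from the published
#' subgenus/section structure of the genus: subgenus Phalaris (the two x = 6
#' species) is sister to subgenus Phalaroides, within which the
#' Phalaroides + Caroliniana clade (P. arundinacea, P. caroliniana) is
#' sister to the Heterachne + Bulbophalaris clade (P. coerulescens sister to
#' P. paradoxa + the two allotetraploids). Branch lengths are omitted; the
#' exact position of P. coerulescens relative to section Bulbophalaris
#' follows the section assignments and is the packaged convention.
#'
#' @return a rooted `phylo` object with 8 leaves; leaf labels use
#'   underscores (see [species_tree_label()]).
#' @export
phalaris_tree <- function() {
  read_newick(paste0(
    "((P_brachystachys,P_canariensis),",
    "((P_arundinacea,P_caroliniana),",
    "(P_coerulescens,(P_paradoxa,(P_aquatica,P_minor)))));"
  ))
}

#' Tree label of a species name
#'
#' @param species character vector like `"P. brachystachys"`.
#' @return labels like `"P_brachystachys"`.
#' @export
species_tree_label <- function(species) {
  gsub("[^A-Za-z0-9]+", "_", gsub("\\.", "", species))
}

#' Taxonomic placement of the study species
#'
#' @return data.frame with columns `species`, `subgenus`, `section`.
#' @export
phalaris_sections <- function() {
  data.frame(
    species = c("P. brachystachys", "P. canariensis", "P. aquatica",
                "P. minor", "P. paradoxa", "P. caroliniana",
                "P. coerulescens", "P. arundinacea"),
    subgenus = c("Phalaris", "Phalaris", "Phalaroides", "Phalaroides",
                 "Phalaroides", "Phalaroides", "Phalaroides", "Phalaroides"),
    section = c("Phalaris", "Phalaris", "Bulbophalaris", "Bulbophalaris",
                "Bulbophalaris", "Caroliniana", "Heterachne", "Phalaroides"),
    stringsAsFactors = FALSE
  )
}

#' Fitch small parsimony
#'
#' Computes the minimum number of unordered character-state changes on a
#' rooted tree and the per-node candidate state sets of the bottom-up Fitch
#' pass. Multifurcations are resolved by pairwise folding of child sets.
#'
#' @param tree a `phylo` object.
#' @param states named character vector mapping every tip label to a state.
#' @return list with `min_changes` (integer) and `node_states` (list of
#'   character vectors indexed by phylo node number: tips first, then
#'   internal nodes).
#' @export
#' @examples
#' tr <- read_newick("((a,b),(c,d));")
#' fitch(tr, c(a = "x", b = "x", c = "y", d = "x"))$min_changes # 1
fitch <- function(tree, states) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  missing <- setdiff(tips, names(states))
  if (length(missing)) {
    stop(sprintf("missing character state for leaf/leaves: %s",
                 paste(missing, collapse = ", ")))
  }
  n_tip <- length(tips)
  n_node <- n_tip + tree$Nnode
  sets <- vector("list", n_node)
  for (i in seq_len(n_tip)) sets[[i]] <- as.character(states[[tips[i]]])
  changes <- 0L
  ord <- ape::reorder.phylo(tree, "postorder")
  edge <- ord$edge
  for (parent in unique(edge[, 1])) {
    children <- edge[edge[, 1] == parent, 2]
    acc <- sets[[children[1]]]
    for (ch in children[-1]) {
      inter <- intersect(acc, sets[[ch]])
      if (length(inter)) {
        acc <- inter
      } else {
        acc <- union(acc, sets[[ch]])
        changes <- changes + 1L
      }
    }
    sets[[parent]] <- acc
  }
  list(min_changes = changes, node_states = sets)
}

# One most-parsimonious reconstruction (top-down refinement of the Fitch
# sets): returns per-node states and the edges (parent, child) on which the
# state changes.
fitch_refine <- function(tree, fit) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  state <- character(n_tip + tree$Nnode)
  state[root] <- fit$node_states[[root]][1]
  edge <- ape::reorder.phylo(tree, "cladewise")$edge
  change_edges <- list()
  for (r in seq_len(nrow(edge))) {
    p <- edge[r, 1]; ch <- edge[r, 2]
    s <- fit$node_states[[ch]]
    state[ch] <- if (state[p] %in% s) state[p] else s[1]
    if (state[ch] != state[p]) {
      lab <- if (ch <= n_tip) tree$tip.label[ch] else sprintf("node%d", ch)
      change_edges[[length(change_edges) + 1]] <- data.frame(
        parent = p, child = ch, child_label = lab,
        from = state[p], to = state[ch], stringsAsFactors = FALSE
      )
    }
  }
  list(states = state,
       changes = if (length(change_edges)) do.call(rbind, change_edges)
                 else data.frame())
}

#' Build the karyotype character matrix of a fixture set
#'
#' Derives the discrete characters used for parsimony mapping from the
#' karyotypes themselves: basic number (via the complement), ploidy, and
#' genome formula (via [assign_genomes()]).
#'
#' @param karyotypes named list of [karyotype()] objects.
#' @return data.frame with one row per species and columns `species`,
#'   `basic_number`, `ploidy`, `genome_formula`, `has_A`, `has_B`, `has_C`.
#' @export
character_matrix <- function(karyotypes) {
  rows <- lapply(karyotypes, function(k) {
    asg <- assign_genomes(k)
    data.frame(
      species = k$species,
      basic_number = k$basic_number,
      ploidy = k$ploidy,
      genome_formula = asg$formula,
      has_A = grepl("A", asg$formula, fixed = TRUE),
      has_B = grepl("B", asg$formula, fixed = TRUE),
      has_C = grepl("C", asg$formula, fixed = TRUE),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Map karyotype characters on the species tree
#'
#' Builds the character matrix from the karyotypes, runs Fitch parsimony
#' for each character on the tree, reports minimal change counts and the
#' change edges of one most-parsimonious reconstruction, and evaluates the
#' genome-distribution statements as boolean checks: genome A confined to
#' section Phalaris, genome C confined to section Bulbophalaris, genome B
#' present in every x = 7 taxon.
#'
#' @param tree a `phylo` object (default [phalaris_tree()]).
#' @param karyotypes named list of [karyotype()] objects covering all
#'   leaves (default: the eight species fixtures).
#' @return list with `matrix`, `parsimony` (per-character min changes and
#'   change edges) and `checks` (named logicals).
#' @export
map_characters <- function(tree = phalaris_tree(), karyotypes = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) == 0) stop("tree has no leaves")
  if (is.null(karyotypes)) {
    fx <- phalaris_fixtures()
    karyotypes <- fx[phalaris_sections()$species]
  }
  cm <- character_matrix(karyotypes)
  cm$tip <- species_tree_label(cm$species)
  missing <- setdiff(tree$tip.label, cm$tip)
  if (length(missing)) {
    stop(sprintf("no karyotype for leaf/leaves: %s", paste(missing, collapse = ", ")))
  }
  chars <- c("basic_number", "ploidy", "genome_formula")
  parsimony <- lapply(chars, function(chname) {
    st <- stats::setNames(as.character(cm[[chname]]), cm$tip)
    fit <- fitch(tree, st)
    ref <- fitch_refine(tree, fit)
    list(character = chname, min_changes = fit$min_changes,
         change_edges = ref$changes)
  })
  names(parsimony) <- chars
  sec <- phalaris_sections()
  cm2 <- merge(cm, sec, by = "species")
  checks <- c(
    genome_A_confined_to_section_Phalaris =
      all(cm2$section[cm2$has_A] == "Phalaris") && any(cm2$has_A),
    genome_C_confined_to_section_Bulbophalaris =
      all(cm2$section[cm2$has_C] == "Bulbophalaris") && any(cm2$has_C),
    genome_B_in_all_x7_taxa = all(cm2$has_B[cm2$basic_number == 7])
  )
  list(matrix = cm, parsimony = parsimony, checks = checks)
}
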