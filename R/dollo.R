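#' Read / write a presence matrix
#'
#' Tab-separated table whose first column holds clade/species labels and
#' whose remaining columns are protein names; cells use the symbols `+`
#' (present), `-` (absent) and `?` (unknown).
#'
#' @param path TSV path.
#' @return Character matrix with row names = clade labels, column names =
#'   protein names, cells in `{+, -, ?}`.
#' @export
read_presence_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stopf("empty presence matrix file: %s", path)
  hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  proteins <- hdr[-1L]
  body <- lines[-1L]
  body <- body[nzchar(body)]
  m <- matrix("?", length(body), length(proteins),
              dimnames = list(NULL, proteins))
  rn <- character(length(body))
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) != length(hdr))
      stopf("presence matrix row %d has %d fields, expected %d", i + 1L,
            length(f), length(hdr))
    rn[i] <- f[1L]
    m[i, ] <- f[-1L]
  }
  rownames(m) <- rn
  if (!all(m %in% c("+", "-", "?")))
    stopf("presence matrix cells must be one of + - ?")
  m
}

#' @rdname read_presence_matrix
#' @param matrix Character matrix of `{+, -, ?}` states.
#' @return `write_presence_matrix()` returns `path` invisibly.
#' @export
write_presence_matrix <- function(matrix, path) {
  hdr <- paste(c("clade", colnames(matrix)), collapse = "\t")
  rows <- vapply(seq_len(nrow(matrix)), function(i)
    paste(c(rownames(matrix)[i], matrix[i, ]), collapse = "\t"), "")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# Branch identifier for the branch ABOVE node `n` in an ape phylo tree:
# tip label for terminal branches, node label (or "node<N>") for internal
# branches, "root" for the stem above the root.
branch_name <- function(tree, n) {
  ntip <- length(tree$tip.label)
  if (n <= ntip) return(tree$tip.label[n])
  root <- ntip + 1L
  if (n == root) return("root")
  lbl <- tree$node.label
  if (!is.null(lbl)) {
    l <- lbl[n - ntip]
    if (!is.na(l) && nzchar(l)) return(l)
  }
  paste0("node", n)
}

# descendant tips (indices) of every node, as a list indexed by node number
node_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  out <- vector("list", nnode)
  for (i in seq_len(ntip)) out[[i]] <- i
  # postorder over edges
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    out[[par]] <- c(out[[par]], out[[ch]])
  }
  out
}

#' Dollo-parsimony gain/loss mapping for one protein
#'
#' Places a single gain of the protein on the branch above the most recent
#' common ancestor of all leaves scored present, then finds the provably
#' minimal set of loss branches explaining every leaf scored absent. Leaves
#' scored `?` (unknown) impose no constraint and inherit the state of the
#' branch governing them. The minimal loss set consists of the maximal
#' subtrees inside the gain clade that contain no present leaf but at least
#' one absent leaf.
#'
#' @param matrix Presence matrix (see [read_presence_matrix()]); row labels
#'   must be a subset of the tree's tip labels. Tips missing from the
#'   matrix count as unknown.
#' @param tree Rooted `phylo` tree (ape). Internal node labels, when
#'   present, name the stem branches above them in the output.
#' @param protein Column name to map.
#' @return Object of class `gain_loss`: list with `protein`, `gain_branch`
#'   (`NA` if the protein is present nowhere), `loss_branches`, `losses`,
#'   and `unknown_leaves`.
#' @export
dollo_map <- function(matrix, tree, protein) {
  if (!protein %in% colnames(matrix))
    stopf("protein '%s' is not a column of the presence matrix", protein)
  if (!all(rownames(matrix) %in% tree$tip.label))
    stopf("presence matrix rows not on the tree: %s",
          paste(setdiff(rownames(matrix), tree$tip.label), collapse = ", "))
  ntip <- length(tree$tip.label)
  states <- rep("?", ntip)
  names(states) <- tree$tip.label
  states[rownames(matrix)] <- matrix[, protein]
  if (all(states == "?"))
    stopf("protein '%s': no leaf has a known state", protein)
  present <- which(states == "+")
  absent <- which(states == "-")
  unknown_leaves <- tree$tip.label[states == "?"]
  if (length(present) == 0L)
    return(structure(list(protein = protein, gain_branch = NA_character_,
                          loss_branches = character(), losses = 0L,
                          unknown_leaves = unknown_leaves),
                     class = "gain_loss"))
  mrca <- if (length(present) == 1L) present else
    ape::getMRCA(tree, present)
  tips <- node_tips(tree)
  # nodes inside the gain clade (mrca subtree)
  clade_nodes <- which(vapply(seq_along(tips), function(n)
    all(tips[[n]] %in% tips[[mrca]]), TRUE))
  parent_of <- integer(ntip + tree$Nnode)
  parent_of[tree$edge[, 2L]] <- tree$edge[, 1L]
  n_present <- vapply(tips, function(tp) sum(tp %in% present), 0L)
  n_absent <- vapply(tips, function(tp) sum(tp %in% absent), 0L)
  loss_nodes <- Filter(function(n) {
    n != mrca && n_present[n] == 0L && n_absent[n] > 0L &&
      n_present[parent_of[n]] > 0L
  }, clade_nodes)
  loss_branches <- sort(vapply(loss_nodes, branch_name, "", tree = tree))
  structure(list(protein = protein,
                 gain_branch = branch_name(tree, mrca),
                 loss_branches = loss_branches,
                 losses = length(loss_branches),
                 unknown_leaves = unknown_leaves),
            class = "gain_loss")
}

#' @export
print.gain_loss <- function(x, ...) {
  cat(sprintf("<gain_loss> %s: gain on '%s', %d loss(es)%s\n", x$protein,
              x$gain_branch, x$losses,
              if (x$losses) paste0(" [", paste(x$loss_branches,
                                               collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' Dollo mapping for every protein column
#'
#' @inheritParams dollo_map
#' @return List of `gain_loss` objects, ordered by column name; class
#'   `gain_loss_set`.
#' @export
dollo_map_all <- function(matrix, tree) {
  cols <- sort(colnames(matrix))
  out <- lapply(cols, function(p)
    tryCatch(dollo_map(matrix, tree, p),
             error = function(e) stopf("column '%s': %s", p,
                                       conditionMessage(e))))
  names(out) <- cols
  structure(out, class = "gain_loss_set")
}

#' @export
print.gain_loss_set <- function(x, ...) {
  for (g in x) print(g)
  invisible(x)
}

#' Convert gain/loss assignments to a report data frame
#' @param x A `gain_loss_set`.
#' @param ... Unused.
#' @return Data frame: protein, gain_branch, loss_branches (comma-joined),
#'   losses.
#' @export
as.data.frame.gain_loss_set <- function(x, ...) {
  data.frame(protein = vapply(x, `[[`, "", "protein"),
             gain_branch = vapply(x, `[[`, "", "gain_branch"),
             loss_branches = vapply(x, function(g)
               paste(g$loss_branches, collapse = ","), ""),
             losses = vapply(x, `[[`, 0L, "losses"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write gain/loss assignments and an annotated Newick tree
#'
#' `write_gainloss_report()` writes the tabular report;
#' `write_annotated_newick()` writes the tree with branch tags of the form
#' `_gain-protein` / `_loss-protein` appended to the label of the node
#' below each tagged branch (plain label characters, so the output stays
#' valid Newick).
#'
#' @param assignments A `gain_loss_set`.
#' @param path Output path.
#' @export
write_gainloss_report <- function(assignments, path) {
  df <- as.data.frame(assignments)
  lines <- sprintf("%s\t%s\t%s\t%d", df$protein, df$gain_branch,
                   df$loss_branches, df$losses)
  writeLines(c("protein\tgain_branch\tloss_branches\tlosses", lines), path)
  invisible(path)
}

#' @rdname write_gainloss_report
#' @param tree Rooted `phylo` the assignments were computed on.
#' @export
write_annotated_newick <- function(assignments, tree, path) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  tags <- rep("", nnode)
  for (g in assignments) {
    for (n in seq_len(nnode)) {
      bn <- branch_name(tree, n)
      if (!is.na(g$gain_branch) && bn == g$gain_branch)
        tags[n] <- paste0(tags[n], "_gain-", g$protein)
      if (bn %in% g$loss_branches)
        tags[n] <- paste0(tags[n], "_loss-", g$protein)
    }
  }
  t2 <- tree
  t2$tip.label <- paste0(tree$tip.label, tags[seq_len(ntip)])
  inl <- (ntip + 1L):nnode
  base <- vapply(inl, branch_name, "", tree = tree)
  t2$node.label <- paste0(ifelse(base == "root", "", base), tags[inl])
  ape::write.tree(t2, file = path)
  invisible(path)
}
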