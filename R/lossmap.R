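# Children lookup for an ape phylo: list indexed by node number.
tree_children <- function(tree) {
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  kids <- vector("list", n_nodes)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; c <- tree$edge[e, 2]
    kids[[p]] <- c(kids[[p]], c)
  }
  kids
}

tree_parent <- function(tree) {
  n_nodes <- ape::Ntip(tree) + tree$Nnode
  par <- rep(NA_integer_, n_nodes)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  par
}

node_label <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  vapply(node, function(v) {
    if (is.na(v)) return(NA_character_)
    if (v <= ntip) return(tree$tip.label[v])
    lab <- if (!is.null(tree$node.label)) tree$node.label[v - ntip] else ""
    if (is.null(lab) || is.na(lab) || !nzchar(lab)) paste0("node_", v) else lab
  }, character(1))
}

# Tip numbers under each node (including the node itself when it is a tip).
descendant_tips <- function(tree, kids) {
  ntip <- ape::Ntip(tree)
  n_nodes <- ntip + tree$Nnode
  out <- vector("list", n_nodes)
  # reverse edge order of a postorder-reordered tree visits children first
  ord <- ape::reorder.phylo(tree, "postorder")$edge
  for (v in seq_len(ntip)) out[[v]] <- v
  for (e in seq_len(nrow(ord))) {
    p <- ord[e, 1]; c <- ord[e, 2]
    out[[p]] <- c(out[[p]], out[[c]])
  }
  out
}

#' Dollo parsimony reconstruction of one presence/absence character
#'
#' Places a single gain on the edge above the last common ancestor of all
#' leaves possessing the character, then finds the minimal set of loss edges
#' below the gain whose subtrees exactly cover the absent leaves — the
#' maximal all-absent subtrees within the gain clade. Under the single-gain
#' constraint this placement minimises the number of losses. Polytomies are
#' supported; losses on polytomy children are counted per child edge.
#'
#' @param tree Rooted `phylo` tree (see [read_newick()]).
#' @param presence Named 0/1 (or logical) vector over all tip labels.
#' @param group Optional group name carried into the output.
#' @return A `hox_events` list: `group`, `gain_edge` (label of the node below
#'   the gain edge, or `NA` when the character is absent everywhere),
#'   `gain_node`, `loss_edges` (tibble `node`, `branch`), `n_losses`, and the
#'   `events` tibble (`branch`, `node`, `group`, `event`).
#' @export
dollo_reconstruct <- function(tree, presence, group = NA_character_) {
  tips <- tree$tip.label
  if (is.logical(presence)) presence <- as.integer(presence)
  missing <- setdiff(tips, names(presence))
  if (length(missing) > 0) {
    abort(paste0("dollo_reconstruct: leaf missing from presence vector: ",
                 paste(missing, collapse = ", ")))
  }
  state <- as.integer(presence[tips] > 0)
  ntip <- ape::Ntip(tree)
  present_tips <- which(state == 1L)

  if (length(present_tips) == 0) {
    ev <- structure(list(
      group = group, gain_edge = NA_character_, gain_node = NA_integer_,
      loss_edges = tibble(node = integer(), branch = character()),
      n_losses = 0L,
      events = tibble(branch = character(), node = integer(),
                      group = character(), event = character())
    ), class = "hox_events")
    return(ev)
  }

  gain_node <- if (length(present_tips) == 1) {
    present_tips
  } else {
    ape::getMRCA(tree, present_tips)
  }

  kids <- tree_children(tree)
  desc <- descendant_tips(tree, kids)
  n_nodes <- ntip + tree$Nnode
  all_absent <- vapply(seq_len(n_nodes),
                       function(v) all(state[desc[[v]]] == 0L), logical(1))

  # maximal all-absent subtrees strictly below the gain node
  loss_nodes <- integer(0)
  walk <- function(v) {
    for (child in kids[[v]]) {
      if (all_absent[child]) {
        loss_nodes <<- c(loss_nodes, child)
      } else {
        walk(child)
      }
    }
  }
  walk(gain_node)

  losses <- tibble(node = loss_nodes, branch = node_label(tree, loss_nodes))
  events <- bind_rows(
    tibble(branch = node_label(tree, gain_node), node = gain_node,
           group = group, event = "gain"),
    tibble(branch = losses$branch, node = losses$node, group = group,
           event = "loss")
  )
  structure(list(
    group = group, gain_edge = node_label(tree, gain_node),
    gain_node = gain_node, loss_edges = losses,
    n_losses = nrow(losses), events = events
  ), class = "hox_events")
}

#' @export
print.hox_events <- function(x, ...) {
  cat("<hox_events>", if (!is.na(x$group)) paste0("group: ", x$group), "\n")
  if (is.na(x$gain_edge)) {
    cat("  absent everywhere (no gain)\n")
  } else {
    cat("  gain above:", x$gain_edge, " losses:", x$n_losses, "\n")
    if (x$n_losses > 0) cat("  loss edges:", paste(x$loss_edges$branch, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-branch gain/loss event table for every orthology group
#'
#' Runs [dollo_reconstruct()] once per group column of a presence matrix and
#' merges the per-branch events. Independent losses of the same group on
#' disjoint branches appear as distinct rows.
#'
#' @param tree Rooted `phylo` tree whose tip labels equal the matrix species.
#' @param presence_matrix Tibble with a `species` column and one 0/1 column
#'   per orthology group (see [complement_presence()]).
#' @return Tibble with columns `branch`, `node`, `group`, `event` sorted by
#'   node; one gain row per group present anywhere, plus loss rows.
#' @export
summarize_events <- function(tree, presence_matrix) {
  groups <- intersect(hox_groups(), names(presence_matrix))
  if (nrow(presence_matrix) == 0 || length(groups) == 0) {
    return(tibble(branch = character(), node = integer(), group = character(),
                  event = character()))
  }
  extra <- setdiff(tree$tip.label, presence_matrix$species)
  if (length(extra) > 0) {
    abort(paste0("summarize_events: tree leaves absent from matrix: ",
                 paste(extra, collapse = ", ")))
  }
  purrr::map(groups, function(g) {
    pres <- setNames(presence_matrix[[g]], presence_matrix$species)
    dollo_reconstruct(tree, pres, group = g)$events
  }) |>
    bind_rows() |>
    arrange(.data$node, .data$group)
}

#' Replay a gain/loss scenario down a tree
#'
#' Leaf states implied by a single gain edge and a set of loss edges: a leaf
#' is present iff it descends from the gain node and from no loss node.
#' Validates that every loss lies strictly below the gain.
#'
#' @param tree Rooted `phylo`.
#' @param gain_node Node number (or tip/node label) carrying the gain, or
#'   `NA` for a character absent everywhere.
#' @param loss_nodes Node numbers (or labels) carrying losses.
#' @return Named 0/1 vector over tip labels.
#' @export
replay_events <- function(tree, gain_node, loss_nodes = integer(0)) {
  ntip <- ape::Ntip(tree)
  resolve <- function(x) {
    if (length(x) == 0) return(integer(0))
    if (is.character(x)) {
      idx <- match(x, c(tree$tip.label, node_label(tree, ntip + seq_len(tree$Nnode))))
      if (any(is.na(idx))) abort(paste0("unknown node label: ",
                                        paste(x[is.na(idx)], collapse = ", ")))
      idx
    } else as.integer(x)
  }
  out <- setNames(rep(0L, ntip), tree$tip.label)
  if (length(gain_node) == 0 || is.na(gain_node)) return(out)
  gain_node <- resolve(gain_node)
  loss_nodes <- resolve(loss_nodes)
  kids <- tree_children(tree)
  desc <- descendant_tips(tree, kids)
  gain_tips <- desc[[gain_node]]
  below <- setdiff(desc_nodes(tree, kids, gain_node), gain_node)
  bad <- setdiff(loss_nodes, below)
  if (length(bad) > 0) {
    abort(paste0("replay_events: loss node(s) not strictly below the gain: ",
                 paste(bad, collapse = ", ")))
  }
  lost_tips <- unique(unlist(desc[loss_nodes]))
  out[tree$tip.label[setdiff(gain_tips, lost_tips)]] <- 1L
  out
}

# All node numbers (tips + internals) in the clade rooted at v.
desc_nodes <- function(tree, kids, v) {
  acc <- v
  stack <- kids[[v]]
  while (length(stack) > 0) {
    x <- stack[[1]]; stack <- stack[-1]
    acc <- c(acc, x)
    stack <- c(stack, kids[[x]])
  }
  acc
}

#' Minimum character changes under unrestricted (Fitch) parsimony
#'
#' Comparison mode for [dollo_reconstruct()]: the minimum number of 0/1 state
#' changes without the single-gain constraint, via sankoff parsimony
#' (handles polytomies). A Fitch count lower than `1 + n_losses` from the
#' Dollo reconstruction signals that independent gains would be more
#' parsimonious than repeated loss.
#'
#' @param tree Rooted `phylo`.
#' @param presence Named 0/1 vector over tip labels.
#' @return Integer minimum number of changes.
#' @export
fitch_changes <- function(tree, presence) {
  state <- as.integer(presence[tree$tip.label] > 0)
  dat <- matrix(as.character(state), ncol = 1,
                dimnames = list(tree$tip.label, NULL))
  pd <- phangorn::phyDat(dat, type = "USER", levels = c("0", "1"))
  as.integer(phangorn::parsimony(tree, pd, method = "sankoff"))
}
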