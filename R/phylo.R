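# Tree ingestion, Grafen branch lengths, Brownian covariance, soft-polytomy
# bookkeeping, and attachment of replicate cases as tip polytomies.
#
# Trees are ape "phylo" objects throughout; this module adds validation and
# the operations the analysis pipeline needs.

#' Parse a Newick string into a validated rooted tree
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants the
#' rest of the package relies on: a single root, unique tip labels, and
#' non-negative branch lengths (when present). Branch lengths are optional;
#' a tree without them can be completed with [grafen_branch_lengths()].
#'
#' Dialect: unquoted labels, optional internal-node labels (ignored),
#' `;`-terminated. NHX extensions are not supported.
#'
#' @param text a Newick string (must end in `;`).
#' @return an object of class `"phylo"`.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' tr$tip.label
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl(";", text, fixed = TRUE)) {
    stop("malformed Newick: no terminating ';' found in string", call. = FALSE)
  }
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) NULL,
    warning = function(w) NULL
  )
  if (is.null(tree) || !inherits(tree, "phylo")) {
    # locate first structurally suspicious position for the error message
    bal <- cumsum((strsplit(text, "")[[1]] == "(") -
                    (strsplit(text, "")[[1]] == ")"))
    pos <- if (any(bal < 0)) which(bal < 0)[1] else nchar(text)
    stop(sprintf("malformed Newick string near position %d", pos),
         call. = FALSE)
  }
  validate_tree(tree)
  tree
}

#' Validate a phylo object against package invariants
#'
#' Checks: class `"phylo"`, unique tip labels, rooted (single root),
#' non-negative branch lengths when present.
#'
#' @param tree a `"phylo"` object.
#' @return the tree, invisibly, if valid; otherwise an error.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate tip labels: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  ntip <- length(tree$tip.label)
  if (ntip >= 2L) {
    # every node except the root must appear exactly once as a child
    children <- tree$edge[, 2]
    if (anyDuplicated(children)) {
      stop("invalid tree: a node has more than one parent", call. = FALSE)
    }
    nnode <- ntip + tree$Nnode
    roots <- setdiff(seq_len(nnode), children)
    if (length(roots) != 1L) {
      stop("invalid tree: expected exactly one root, found ",
           length(roots), call. = FALSE)
    }
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    stop("negative branch lengths are not allowed", call. = FALSE)
  }
  invisible(tree)
}

#' Count soft polytomies
#'
#' A soft polytomy is an internal node (the root included) with more than
#' two children. Each such node counts exactly once regardless of how many
#' extra children it bears, matching the convention of subtracting one
#' degree of freedom per unresolved node in hypothesis tests (see
#' [corrected_df()]).
#'
#' @param tree a `"phylo"` object.
#' @return a `polytomy_report`: list with `n_soft_polytomies` and `node_ids`
#'   (ape node numbers).
#' @examples
#' count_soft_polytomies(parse_newick("(A,B,C,D,E);"))$n_soft_polytomies
#' @export
count_soft_polytomies <- function(tree) {
  validate_tree(tree)
  n_children <- tabulate(tree$edge[, 1],
                         nbins = length(tree$tip.label) + tree$Nnode)
  ids <- which(n_children > 2L)
  structure(
    list(n_soft_polytomies = length(ids), node_ids = as.integer(ids)),
    class = "polytomy_report"
  )
}

#' @export
print.polytomy_report <- function(x, ...) {
  cat("Soft polytomies (internal nodes with >2 children):",
      x$n_soft_polytomies, "\n")
  if (x$n_soft_polytomies > 0)
    cat("  node ids:", paste(x$node_ids, collapse = ", "), "\n")
  invisible(x)
}

# number of tips descending from each node (tips count themselves);
# postorder guarantees every child is accumulated before its parent is used
.n_descendant_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  ndesc <- integer(nnode)
  ndesc[seq_len(ntip)] <- 1L
  for (i in ape::postorder(tree)) {
    e <- tree$edge[i, ]
    ndesc[e[1]] <- ndesc[e[1]] + ndesc[e[2]]
  }
  ndesc
}

#' Assign Grafen branch lengths
#'
#' Sets each node's height to `(d - 1) / (n - 1)`, where `d` is the number
#' of tips descending from the node and `n` the total number of tips (the
#' height exponent rho is fixed at 1). Tips sit at height 0, the root at
#' height 1, and each branch length is the parent height minus the child
#' height, so the output is ultrametric with unit root-to-tip distance.
#' Any existing branch lengths are overwritten.
#'
#' @param tree a rooted `"phylo"` object with at least 2 tips.
#' @return the tree with Grafen branch lengths.
#' @examples
#' tr <- grafen_branch_lengths(parse_newick("((A,B),(C,D));"))
#' ape::is.ultrametric(tr)
#' @export
grafen_branch_lengths <- function(tree) {
  validate_tree(tree)
  ntip <- length(tree$tip.label)
  if (ntip < 2L) stop("Grafen heights are undefined for a 1-tip tree",
                      call. = FALSE)
  ndesc <- .n_descendant_tips(tree)
  height <- (ndesc - 1) / (ntip - 1)
  tree$edge.length <- height[tree$edge[, 1]] - height[tree$edge[, 2]]
  tree
}

#' Brownian-motion phylogenetic covariance matrix
#'
#' Entry (i, j) is the branch-length distance from the root to the most
#' recent common ancestor of tips i and j; the diagonal holds root-to-tip
#' distances. This is the trait covariance structure (up to the rate
#' sigma^2) implied by Brownian evolution along the tree.
#'
#' @param tree a `"phylo"` object with all branch lengths present.
#' @return a symmetric positive-semidefinite matrix with tip labels as
#'   dimnames.
#' @export
phylo_covariance <- function(tree) {
  validate_tree(tree)
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths; run grafen_branch_lengths() first",
         call. = FALSE)
  }
  if (anyNA(tree$edge.length)) {
    stop("tree has missing branch lengths; run grafen_branch_lengths() first",
         call. = FALSE)
  }
  V <- ape::vcv.phylo(tree)
  V[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Attach replicate cases to tree tips as soft polytomies
#'
#' Multiple measurements (cases) per species enter the comparative analysis
#' as near-zero-length polytomies at the tips: each tip with `k > 1` cases
#' is replaced by an internal node bearing `k` case-labelled tips on
#' branches of length `epsilon`, and the original terminal branch is
#' shortened by `epsilon` so total tree height is unchanged. A tip with a
#' single case is simply relabelled to the case id. Tips absent from
#' `case_map` are left untouched.
#'
#' `epsilon` is strictly positive (rather than 0) so the resulting
#' covariance matrix stays nonsingular.
#'
#' @param tree a `"phylo"` object with branch lengths.
#' @param case_map named list: species tip label -> character vector of case
#'   ids.
#' @param epsilon small positive branch length for replicate tips; must be
#'   smaller than every terminal branch being split.
#' @return list with `tree` (augmented) and `polytomies`
#'   (a [count_soft_polytomies()] report for the augmented tree).
#' @export
attach_replicates <- function(tree, case_map, epsilon = 1e-6) {
  validate_tree(tree)
  if (is.null(tree$edge.length))
    stop("tree needs branch lengths before attaching replicates",
         call. = FALSE)
  stopifnot(is.list(case_map), epsilon > 0)
  if (is.null(names(case_map)) || any(!nzchar(names(case_map))))
    stop("case_map must be a named list (species -> case ids)", call. = FALSE)
  missing_sp <- setdiff(names(case_map), tree$tip.label)
  if (length(missing_sp) > 0)
    stop("species not in tree: ", paste(missing_sp, collapse = ", "),
         call. = FALSE)
  all_ids <- unlist(case_map, use.names = FALSE)
  if (anyDuplicated(all_ids))
    stop("case ids must be unique across species", call. = FALSE)

  ntip <- length(tree$tip.label)
  term_len <- tree$edge.length[match(seq_len(ntip), tree$edge[, 2])]
  for (sp in names(case_map)) {
    k <- length(case_map[[sp]])
    if (k > 1 && term_len[match(sp, tree$tip.label)] <= epsilon) {
      stop(sprintf(
        "epsilon (%g) is not smaller than the terminal branch of '%s' (%g)",
        epsilon, sp, term_len[match(sp, tree$tip.label)]), call. = FALSE)
    }
  }

  # rebuild via Newick text: substitute each replicated tip by a star
  # cluster; relabel singletons
  fmt <- function(x) sprintf("%.15g", x)
  subs <- lapply(names(case_map), function(sp) {
    ids <- case_map[[sp]]
    b <- term_len[match(sp, tree$tip.label)]
    if (length(ids) == 1L) {
      paste0(ids, ":", fmt(b))
    } else {
      paste0("(", paste0(ids, ":", fmt(epsilon), collapse = ","), "):",
             fmt(b - epsilon))
    }
  })
  names(subs) <- names(case_map)

  nwk <- .write_newick(tree, tip_override = subs)
  out <- ape::read.tree(text = nwk)
  validate_tree(out)
  list(tree = out, polytomies = count_soft_polytomies(out))
}

# Recursive Newick writer; tip_override maps tip label -> replacement
# "label:length" fragment (already formatted, including branch length).
.write_newick <- function(tree, tip_override = list()) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fmt <- function(x) sprintf("%.15g", x)
  rec <- function(node, blen) {
    if (node <= ntip) {
      lab <- tree$tip.label[node]
      if (!is.null(tip_override[[lab]])) return(tip_override[[lab]])
      if (is.na(blen)) return(lab)
      return(paste0(lab, ":", fmt(blen)))
    }
    es <- kids[[as.character(node)]]
    parts <- vapply(es, function(e) {
      rec(tree$edge[e, 2],
          if (is.null(tree$edge.length)) NA_real_ else tree$edge.length[e])
    }, character(1))
    core <- paste0("(", paste(parts, collapse = ","), ")")
    if (is.na(blen)) core else paste0(core, ":", fmt(blen))
  }
  paste0(rec(root, NA_real_), ";")
}

#' Write a tree to a Newick string
#'
#' @param tree a `"phylo"` object.
#' @param digits ignored; full double precision is always written.
#' @return a Newick string.
#' @export
write_newick <- function(tree, digits = NULL) {
  validate_tree(tree)
  .write_newick(tree)
}
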