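#' Build the super-node genotype network
#'
#' The network has one super-node per group (disease condition) and one node
#' per distinct genotype superset. A node is linked to a group's super-node
#' iff at least one individual of that group carries the superset; the edge
#' weight w is that individual count, so `1 <= w <= P` and the weights into a
#' super-node sum to the group size.
#'
#' @param freq A `superset_freq` from [superset_table()].
#' @return A `genotype_network` object with fields `groups` (super-node
#'   labels in declared order), `nodes` (superset keys, lexicographic),
#'   `edges` (tibble `superset`, `group`, `weight`), and `P` (total
#'   individuals).
#' @examples
#' cohort <- generate_cohort(synth_preset("acs-like", seed = 1))
#' net <- build_network(superset_table(cohort))
#' glance(net)
#' @export
build_network <- function(freq) {
  stopifnot(inherits(freq, "superset_freq"))
  groups <- attr(freq, "groups")
  if (nrow(freq) == 0 || sum(as.matrix(freq[groups])) == 0) {
    stop("superset table has no positive counts", call. = FALSE)
  }
  edges <- tidyr::pivot_longer(tibble::as_tibble(freq),
                               dplyr::all_of(groups),
                               names_to = "group", values_to = "weight")
  edges <- edges[edges$weight > 0, c("superset", "group", "weight")]
  edges <- edges[order_c(edges$superset), , drop = FALSE]
  nodes <- unique(edges$superset)
  nodes <- nodes[order_c(nodes)]
  structure(
    list(groups = groups,
         nodes = nodes,
         edges = tibble::as_tibble(edges),
         P = sum(edges$weight)),
    class = "genotype_network"
  )
}

#' @export
print.genotype_network <- function(x, ...) {
  cat("Genotype super-node network\n")
  cat("  super-nodes (k): ", length(x$groups), " (",
      paste(x$groups, collapse = ", "), ")\n", sep = "")
  cat("  nodes (N):       ", length(x$nodes), "\n", sep = "")
  cat("  edges:           ", nrow(x$edges), "\n", sep = "")
  cat("  individuals (P): ", x$P, "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname build_network
#' @param x A `genotype_network`.
#' @param ... Unused.
#' @export
tidy.genotype_network <- function(x, ...) x$edges

#' @rdname build_network
#' @export
glance.genotype_network <- function(x, ...) {
  tibble::tibble(k = length(x$groups), N = length(x$nodes),
                 n_edges = nrow(x$edges), P = x$P)
}

#' Partition network nodes by super-node membership
#'
#' Assigns every node (superset) to the class keyed by the exact set of
#' super-nodes it touches: group-specific classes (one group only), pairwise
#' shared classes, up to the class shared by all k groups. All `2^k - 1`
#' classes are reported, including empty ones.
#'
#' @param net A `genotype_network`.
#' @return A tibble with columns `superset` and `membership` (group labels
#'   joined by `"+"` in declared order), carrying a `counts` attribute; see
#'   [partition_counts()].
#' @export
partition_nodes <- function(net) {
  stopifnot(inherits(net, "genotype_network"))
  groups <- net$groups
  member <- net$edges |>
    dplyr::group_by(.data$superset) |>
    dplyr::summarise(
      membership = paste(groups[sort(match(unique(.data$group), groups))],
                         collapse = "+"),
      .groups = "drop")
  member <- member[match(net$nodes, member$superset), , drop = FALSE]
  classes <- membership_classes(groups)
  counts <- tibble::tibble(
    membership = classes,
    n_groups = lengths(strsplit(classes, "+", fixed = TRUE)),
    n_nodes = vapply(classes, function(cl) sum(member$membership == cl),
                     integer(1), USE.NAMES = FALSE)
  )
  structure(member, counts = counts,
            class = c("node_partition", class(tibble::tibble())))
}

# All 2^k - 1 nonempty group subsets, labels joined by "+" in declared order.
membership_classes <- function(groups) {
  k <- length(groups)
  unlist(lapply(seq_len(k), function(size) {
    apply(utils::combn(groups, size), 2, paste, collapse = "+")
  }))
}

#' Per-class node counts of a partition
#'
#' @param partition Output of [partition_nodes()].
#' @return Tibble with `membership`, `n_groups`, `n_nodes` over all
#'   `2^k - 1` membership classes (zeros included).
#' @export
partition_counts <- function(partition) attr(partition, "counts")

#' Group-specific fraction of a network
#'
#' Nodes basis: the fraction of nodes whose super-node membership is exactly
#' `{group}`, out of all N nodes. Individuals basis: the summed edge weights
#' on those group-specific nodes, out of the total edge weight (every
#' individual contributes weight 1 to exactly one edge, so the denominator
#' equals P).
#'
#' @param net A `genotype_network`.
#' @param group A super-node label.
#' @param basis `"nodes"` or `"individuals"`.
#' @return A fraction in `[0, 1]`.
#' @export
specific_fraction <- function(net, group, basis = c("nodes", "individuals")) {
  stopifnot(inherits(net, "genotype_network"))
  basis <- match.arg(basis)
  if (!group %in% net$groups) {
    stop("unknown group: ", group, call. = FALSE)
  }
  part <- partition_nodes(net)
  specific <- part$superset[part$membership == group]
  if (basis == "nodes") {
    length(specific) / length(net$nodes)
  } else {
    sum(net$edges$weight[net$edges$superset %in% specific]) /
      sum(net$edges$weight)
  }
}

#' Export a network as a Pajek NET file
#'
#' Vertices are 1-based: super-nodes take ids `1..k` in declared group order,
#' superset nodes follow in lexicographic order. Edges are undirected
#' `<node_id> <supernode_id> <weight>` lines with integer weights. Output is
#' byte-stable for a given network.
#'
#' @param net A `genotype_network`.
#' @param path Output file path, or `NULL` to return the lines only.
#' @return The NET lines, invisibly.
#' @export
write_pajek <- function(net, path = NULL) {
  stopifnot(inherits(net, "genotype_network"))
  if (length(net$nodes) == 0) stop("empty network", call. = FALSE)
  k <- length(net$groups)
  labels <- c(net$groups, net$nodes)
  lines <- c(
    paste0("*Vertices ", k + length(net$nodes)),
    sprintf("%d \"%s\"", seq_along(labels), labels),
    "*Edges",
    sprintf("%d %d %d",
            k + match(net$edges$superset, net$nodes),
            match(net$edges$group, net$groups),
            as.integer(net$edges$weight))
  )
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Read a Pajek NET file written by [write_pajek()]
#'
#' @param path Path to a NET file.
#' @return Tibble with columns `superset`, `group`, `weight`.
#' @export
read_pajek <- function(path) {
  lines <- readLines(path)
  n_vert <- as.integer(sub("^\\*Vertices\\s+", "", lines[1]))
  vert_lines <- lines[2:(1 + n_vert)]
  labels <- sub('^\\d+ "(.*)"$', "\\1", vert_lines)
  edge_lines <- lines[(3 + n_vert):length(lines)]
  parts <- do.call(rbind, strsplit(edge_lines, " ", fixed = TRUE))
  tibble::tibble(
    superset = labels[as.integer(parts[, 1])],
    group = labels[as.integer(parts[, 2])],
    weight = as.integer(parts[, 3])
  )
}

#' Write the TSV partition report
#'
#' Columns: `superset`, `membership`, then the per-group individual counts.
#'
#' @param net A `genotype_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition_report <- function(net, path) {
  part <- partition_nodes(net)
  wide <- tidyr::pivot_wider(net$edges, names_from = "group",
                             values_from = "weight", values_fill = 0L)
  missing_groups <- setdiff(net$groups, names(wide))
  for (g in missing_groups) wide[[g]] <- 0L
  out <- dplyr::left_join(tibble::as_tibble(part), wide, by = "superset")
  out <- out[c("superset", "membership", net$groups)]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Plot a genotype network as a bipartite diagram
#'
#' Super-nodes are drawn on the upper row, superset nodes on the lower row
#' grouped by membership class; segment width is the edge weight (number of
#' individuals).
#'
#' @param object A `genotype_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.genotype_network <- function(object, ...) {
  part <- partition_nodes(object)
  ord <- order(part$membership, method = "radix")
  node_pos <- tibble::tibble(
    superset = part$superset[ord],
    membership = part$membership[ord],
    x = seq_along(ord), y = 0
  )
  k <- length(object$groups)
  super_pos <- tibble::tibble(
    group = object$groups,
    x = (seq_len(k) - 0.5) * nrow(node_pos) / k, y = 1
  )
  seg <- object$edges |>
    dplyr::left_join(node_pos, by = "superset") |>
    dplyr::left_join(super_pos, by = "group", suffix = c("", "_s"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$x_s,
                   yend = .data$y_s, linewidth = .data$weight),
      alpha = 0.4) +
    ggplot2::geom_point(
      data = node_pos,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$membership),
      size = 2) +
    ggplot2::geom_label(
      data = super_pos,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$group)) +
    ggplot2::scale_linewidth(range = c(0.2, 2)) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "membership", linewidth = "individuals (w)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
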