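# Association-rule mining of CHM co-prescriptions and the co-prescription
# network. A transaction is one patient-day prescription event; its item
# set is the distinct CHM products dispensed that day. All rule statistics
# count transactions.

#' Build the transaction set from CHM prescription rows
#'
#' @param chm_prescriptions prescription rows; non-CHM classes are dropped
#'   if a `class` column is present.
#' @return object of class `transaction_set`: `items` (long tibble `tid`,
#'   `patient_id`, `date`, `product_code`, deduplicated within
#'   transaction) and `n_total` (number of transactions).
#' @export
build_transactions <- function(chm_prescriptions) {
  rx <- tibble::as_tibble(chm_prescriptions)
  if ("class" %in% names(rx)) rx <- rx[rx$class == "CHM", , drop = FALSE]
  if (nrow(rx) == 0) {
    return(structure(list(items = tibble::tibble(
      tid = integer(), patient_id = character(),
      date = as.Date(character()), product_code = character()),
      n_total = 0L), class = "transaction_set"))
  }
  items <- rx |>
    dplyr::distinct(.data$patient_id, .data$date, .data$product_code) |>
    dplyr::arrange(.data$patient_id, .data$date, .data$product_code)
  key <- paste(items$patient_id, items$date)
  tid <- match(key, unique(key))
  items$tid <- tid
  structure(list(items = items[, c("tid", "patient_id", "date",
                                   "product_code")],
                 n_total = max(tid)),
            class = "transaction_set")
}

#' @export
print.transaction_set <- function(x, ...) {
  cat("<transaction_set>", x$n_total, "transactions,",
      length(unique(x$items$product_code)), "products\n")
  invisible(x)
}

#' Association-rule statistics for one product pair
#'
#' Support, confidence and lift from the transaction counts:
#' support = 100 * freq_xy / n_total;
#' confidence(X -> Y) = 100 * freq_xy / freq_x;
#' p(Y) = 100 * freq_y / n_total; lift = confidence / p(Y).
#' Values are returned at full precision; round with [round_half_up()]
#' (2 decimals) for table rendering.
#'
#' @param freq_x,freq_y marginal transaction counts of antecedent and
#'   consequent.
#' @param freq_xy joint transaction count.
#' @param n_total total number of transactions.
#' @return list with `support_pct`, `confidence_pct`, `p_y_pct`, `lift`.
#' @export
#' @examples
#' s <- rule_stats(399, 557, 145, 7376)
#' round_half_up(c(s$support_pct, s$confidence_pct, s$lift))
rule_stats <- function(freq_x, freq_y, freq_xy, n_total) {
  if (n_total <= 0 || freq_x <= 0 || freq_y <= 0)
    stop_data("zero denominator in rule statistics")
  if (freq_xy < 0 || freq_xy > min(freq_x, freq_y) ||
      max(freq_x, freq_y) > n_total)
    stop_data("inconsistent counts: need 0 <= freq_xy <= min(freq_x, freq_y) <= n_total")
  support <- 100 * freq_xy / n_total
  confidence <- 100 * freq_xy / freq_x
  p_y <- 100 * freq_y / n_total
  list(support_pct = support, confidence_pct = confidence,
       p_y_pct = p_y, lift = confidence / p_y)
}

#' Orient a product pair into an association rule
#'
#' The antecedent (left-hand side) is the product with the smaller
#' marginal frequency — the orientation that maximises confidence; ties
#' break lexicographically by product code.
#'
#' @param a,b product codes.
#' @param freq_a,freq_b their marginal transaction counts.
#' @return character vector `c(x, y)`, antecedent first.
#' @export
orient_rule <- function(a, b, freq_a, freq_b) {
  if (freq_a <= 0 || freq_b <= 0) stop_data("marginal frequencies must be positive")
  if (freq_a < freq_b) c(a, b)
  else if (freq_b < freq_a) c(b, a)
  else if (a <= b) c(a, b) else c(b, a)
}

# tally all co-occurring pairs (unordered) and marginals of a transaction set
.pair_counts <- function(ts) {
  items <- ts$items
  marg <- table(items$product_code)
  by_tid <- split(items$product_code, items$tid)
  by_tid <- by_tid[lengths(by_tid) >= 2]
  if (length(by_tid) == 0) {
    return(list(marginals = marg,
                pairs = tibble::tibble(a = character(), b = character(),
                                       freq_xy = integer())))
  }
  pair_mat <- do.call(cbind, lapply(by_tid, function(pr) combn(sort(pr), 2)))
  key <- paste(pair_mat[1, ], pair_mat[2, ], sep = "\r")
  tab <- table(key)
  ab <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
  list(marginals = marg,
       pairs = tibble::tibble(a = ab[, 1], b = ab[, 2],
                              freq_xy = as.integer(tab)))
}

#' Top co-prescription rules
#'
#' Tallies every co-occurring product pair, orients each with
#' [orient_rule()], computes [rule_stats()], and ranks by joint frequency
#' (then support, lift, lexicographic antecedent/consequent).
#'
#' @param ts a `transaction_set`.
#' @param k number of rules to return (default 5); `Inf` for all.
#' @param min_freq_xy minimum joint count (default 1).
#' @return tibble with one row per rule: `x`, `y`, `freq_x`, `freq_y`,
#'   `freq_xy`, `support_pct`, `confidence_pct`, `lift` (full precision).
#' @export
top_rules <- function(ts, k = 5, min_freq_xy = 1) {
  stopifnot(inherits(ts, "transaction_set"))
  if (ts$n_total == 0) stop_data("empty transaction set")
  pc <- .pair_counts(ts)
  pairs <- pc$pairs[pc$pairs$freq_xy >= min_freq_xy, , drop = FALSE]
  if (nrow(pairs) == 0) {
    return(tibble::tibble(x = character(), y = character(),
                          freq_x = integer(), freq_y = integer(),
                          freq_xy = integer(), support_pct = numeric(),
                          confidence_pct = numeric(), lift = numeric()))
  }
  marg <- pc$marginals
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$a[i]; b <- pairs$b[i]
    fa <- as.integer(marg[[a]]); fb <- as.integer(marg[[b]])
    xy <- orient_rule(a, b, fa, fb)
    fx <- if (xy[1] == a) fa else fb
    fy <- if (xy[1] == a) fb else fa
    st <- rule_stats(fx, fy, pairs$freq_xy[i], ts$n_total)
    tibble::tibble(x = xy[1], y = xy[2], freq_x = fx, freq_y = fy,
                   freq_xy = pairs$freq_xy[i],
                   support_pct = st$support_pct,
                   confidence_pct = st$confidence_pct, lift = st$lift)
  })
  out <- dplyr::bind_rows(rows)
  out <- out[order(-out$freq_xy, -out$support_pct, -out$lift,
                   out$x, out$y), , drop = FALSE]
  head(out, n = if (is.finite(k)) k else nrow(out))
}

#' Cumulative dispensed mass of one product
#'
#' Average daily dose (g) times average prescription duration (days)
#' times prescription-row count, over the product's CHM rows.
#'
#' @param product product code.
#' @param chm_prescriptions prescription rows with `product_code`,
#'   `daily_dose_g`, `days`.
#' @return grams (full precision).
#' @export
dosage <- function(product, chm_prescriptions) {
  rx <- tibble::as_tibble(chm_prescriptions)
  if ("class" %in% names(rx)) rx <- rx[rx$class == "CHM", , drop = FALSE]
  rows <- rx[rx$product_code == product, , drop = FALSE]
  if (nrow(rows) == 0) stop_data("product `%s` has no prescriptions", product)
  mean(rows$daily_dose_g) * mean(rows$days) * nrow(rows)
}

#' Render the rules table
#'
#' Two-decimal (half-up) rendering of the rule statistics, plus marginal
#' dosages when prescriptions are supplied — the layout of the printed
#' top-co-prescription table.
#'
#' @param rules tibble from [top_rules()].
#' @param chm_prescriptions optional prescription rows for the dosage
#'   columns.
#' @return tibble.
#' @export
render_rules <- function(rules, chm_prescriptions = NULL) {
  out <- tibble::tibble(
    lhs = rules$x, rhs = rules$y,
    freq_x = rules$freq_x, freq_y = rules$freq_y,
    freq_xy = rules$freq_xy,
    support_pct = round_half_up(rules$support_pct, 2),
    confidence_pct = round_half_up(rules$confidence_pct, 2),
    lift = round_half_up(rules$lift, 2))
  if (!is.null(chm_prescriptions)) {
    out$dosage_x <- round_half_up(vapply(
      rules$x, dosage, numeric(1), chm_prescriptions = chm_prescriptions), 0)
    out$dosage_y <- round_half_up(vapply(
      rules$y, dosage, numeric(1), chm_prescriptions = chm_prescriptions), 0)
  }
  out
}

#' Build the co-prescription network
#'
#' Nodes are products meeting `node_min_freq` (sized by prescription
#' frequency, typed single herb vs formula, optionally carrying total
#' dispensed grams); edges connect pairs meeting `edge_min_support_pct`
#' and carry support, lift and joint frequency. Clusters are connected
#' components.
#'
#' @param rules tibble from [top_rules()] (any subset of rules).
#' @param chm_prescriptions optional prescription rows for node kind and
#'   dosage attributes.
#' @param node_min_freq minimum marginal frequency for a node.
#' @param edge_min_support_pct minimum support (%) for an edge.
#' @return object of class `coprescription_graph` wrapping an
#'   [igraph::graph] with node attributes `kind`, `freq`, `dosage_g`,
#'   `cluster_id` and edge attributes `support_pct`, `lift`, `freq_xy`.
#' @export
build_graph <- function(rules, chm_prescriptions = NULL,
                        node_min_freq = 1, edge_min_support_pct = 0) {
  nodes <- tibble::tibble(
    code = c(rules$x, rules$y),
    freq = c(rules$freq_x, rules$freq_y)) |>
    dplyr::distinct() |>
    dplyr::filter(.data$freq >= node_min_freq)
  edges <- rules[rules$support_pct >= edge_min_support_pct &
                   rules$x %in% nodes$code & rules$y %in% nodes$code, ,
                 drop = FALSE]
  if (nrow(nodes) == 0) {
    warning("thresholds exclude all nodes; empty graph")
    g <- igraph::make_empty_graph(directed = FALSE)
    return(structure(list(graph = g, nodes = nodes, edges = edges),
                     class = "coprescription_graph"))
  }
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = edges$x, to = edges$y,
                   support_pct = edges$support_pct, lift = edges$lift,
                   freq_xy = edges$freq_xy),
    directed = FALSE,
    vertices = data.frame(name = nodes$code, freq = nodes$freq))
  if (!is.null(chm_prescriptions)) {
    rx <- tibble::as_tibble(chm_prescriptions)
    if ("class" %in% names(rx)) rx <- rx[rx$class == "CHM", , drop = FALSE]
    kind <- vapply(igraph::V(g)$name, function(code) {
      kk <- rx$product_kind[rx$product_code == code]
      if (length(kk) > 0) kk[1] else NA_character_
    }, character(1))
    dg <- vapply(igraph::V(g)$name, function(code) {
      if (code %in% rx$product_code) dosage(code, rx) else NA_real_
    }, numeric(1))
    igraph::V(g)$kind <- kind
    igraph::V(g)$dosage_g <- dg
  }
  comp <- igraph::components(g)
  igraph::V(g)$cluster_id <- comp$membership
  structure(list(graph = g,
                 nodes = tibble::tibble(code = igraph::V(g)$name,
                                        freq = igraph::V(g)$freq,
                                        cluster_id = comp$membership),
                 edges = edges, n_clusters = comp$no),
            class = "coprescription_graph")
}

#' @export
print.coprescription_graph <- function(x, ...) {
  cat("<coprescription_graph>", nrow(x$nodes), "nodes,",
      igraph::ecount(x$graph), "edges,", x$n_clusters, "clusters\n")
  invisible(x)
}

#' Cluster membership of a co-prescription graph
#'
#' @param graph a `coprescription_graph`.
#' @return list of character vectors, one per connected component, sorted
#'   by decreasing size.
#' @export
graph_clusters <- function(graph) {
  sp <- split(graph$nodes$code, graph$nodes$cluster_id)
  unname(sp[order(-lengths(sp))])
}

#' Export the network as GraphML plus a JSON edge list
#'
#' @param graph a `coprescription_graph`.
#' @param graphml_path,json_path output paths (either may be `NULL`).
#' @return invisibly, the paths written.
#' @export
write_graph_files <- function(graph, graphml_path = NULL, json_path = NULL) {
  if (!is.null(graphml_path))
    igraph::write_graph(graph$graph, graphml_path, format = "graphml")
  if (!is.null(json_path))
    jsonlite::write_json(
      list(nodes = graph$nodes, edges = graph$edges),
      json_path, dataframe = "rows", auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  invisible(c(graphml_path, json_path))
}
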