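# Joint product-status state space --------------------------------------------
#
# Every modelled product has exactly three use statuses (never / current /
# former), so a market with N products has 3^N joint population stocks.  From
# each status a product has a single admissible move: never -> current
# (initiation), current -> former (cessation), former -> current (relapse).
# A transition flow changes a non-empty subset of products simultaneously, each
# changed product performing its admissible move, giving 2^N - 1 outflows per
# stock and 3^N * (2^N - 1) flows in total.

STATUS_LEVELS <- c("never", "current", "former")
STATUS_CODES <- c(never = "N", current = "C", former = "F")

#' Default product labels
#'
#' The first product is always the combustible cigarette; the second and third
#' default to the two potentially reduced-risk product (PRRP) categories.
#'
#' @param n_products Number of products (>= 1).
#' @return Character vector of length `n_products`.
#' @export
default_products <- function(n_products) {
  base <- c("cigarette", "ecig", "thp")
  if (n_products <= 3L) {
    base[seq_len(n_products)]
  } else {
    c(base, paste0("product", seq(4L, n_products)))
  }
}

state_label <- function(statuses) {
  paste(STATUS_CODES[statuses], collapse = ".")
}

#' Enumerate the joint product-status state space
#'
#' Lists every combination of never/current/former status across `n_products`
#' products, in a canonical lexicographic order: the first product varies
#' slowest and statuses are ordered never < current < former.  The order is
#' deterministic so serialised state ids are stable across runs.
#'
#' @param n_products Number of coexisting products (integer >= 1).
#' @param products Product labels; the first is the combustible cigarette.
#' @return A tibble with one row per joint state (`3^n_products` rows):
#'   `state_id`, a compact `state` label (e.g. `"C.N"` for a current smoker who
#'   has never used the second product), and one status column per product.
#' @examples
#' enumerate_states(2)
#' @export
enumerate_states <- function(n_products, products = default_products(n_products)) {
  if (!is.numeric(n_products) || length(n_products) != 1L || is.na(n_products) ||
      n_products < 1 || n_products != as.integer(n_products)) {
    abort("`n_products` must be a single integer >= 1.")
  }
  n <- as.integer(n_products)
  if (length(products) != n || anyDuplicated(products) > 0L) {
    abort("`products` must be `n_products` distinct labels.")
  }
  # expand.grid varies its first factor fastest; feeding the products reversed
  # and flipping the columns back makes product 1 the slowest-varying digit.
  combos <- expand.grid(rep(list(STATUS_LEVELS), n),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  combos <- combos[, rev(seq_len(n)), drop = FALSE]
  names(combos) <- products
  out <- tibble::as_tibble(combos)
  out <- tibble::add_column(
    out,
    state_id = seq_len(nrow(out)),
    state = vapply(seq_len(nrow(out)),
                   function(i) state_label(unlist(combos[i, ], use.names = FALSE)),
                   character(1)),
    .before = 1
  )
  attr(out, "products") <- products
  out
}

state_products <- function(states) {
  prods <- attr(states, "products")
  if (!is.null(prods)) return(prods)
  setdiff(names(states), c("state_id", "state"))
}

#' The single admissible move from a product status
#'
#' Each status has exactly one outgoing move: never users can initiate, current
#' users can quit, and former users can relapse.
#'
#' @param status One of `"never"`, `"current"`, `"former"`.
#' @return A list with elements `to` (destination status) and `move`
#'   (`"initiate"`, `"quit"` or `"relapse"`).
#' @export
admissible_move <- function(status) {
  status <- match.arg(status, STATUS_LEVELS)
  switch(status,
    never   = list(to = "current", move = "initiate"),
    current = list(to = "former",  move = "quit"),
    former  = list(to = "current", move = "relapse")
  )
}

#' Enumerate the admissible transition flows of a state space
#'
#' From every joint state, each non-empty subset of products may transition
#' simultaneously, every changed product performing its single admissible move
#' ([admissible_move()]).  A complete `3^N` state enumeration therefore yields
#' `2^N - 1` outflows per stock and `3^N * (2^N - 1)` flows in total.
#'
#' @param states A complete state enumeration from [enumerate_states()].
#' @return A tibble with one row per flow: `flow_id`, `from_id`/`to_id` state
#'   ids, `from`/`to` state labels, `changed` (changed product indices joined
#'   with `"+"`), `moves` (per-product move kinds), `n_changed`, and one
#'   `move_<product>` column giving that product's move kind (`NA` when the
#'   product is unchanged).
#' @examples
#' nrow(enumerate_flows(enumerate_states(3))) # 189
#' @export
enumerate_flows <- function(states) {
  products <- state_products(states)
  n <- length(products)
  if (n < 1L) abort("`states` has no product status columns.")
  canon <- enumerate_states(n, products)
  if (nrow(states) != 3^n || anyDuplicated(states$state) > 0L ||
      !setequal(states$state, canon$state)) {
    abort(sprintf("`states` must be a complete enumeration of all %d joint states.", 3^n))
  }

  subsets <- lapply(seq_len(2^n - 1L), function(mask) {
    which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) > 0L)
  })
  status_mat <- as.matrix(states[, products, drop = FALSE])

  rows <- vector("list", nrow(states) * length(subsets))
  k <- 0L
  for (i in seq_len(nrow(states))) {
    from_status <- status_mat[i, ]
    for (sub in subsets) {
      to_status <- from_status
      kinds <- character(length(sub))
      for (j in seq_along(sub)) {
        mv <- admissible_move(from_status[[sub[j]]])
        to_status[sub[j]] <- mv$to
        kinds[j] <- mv$move
      }
      move_by_product <- rep(NA_character_, n)
      move_by_product[sub] <- kinds
      k <- k + 1L
      rows[[k]] <- c(
        list(
          from_id = states$state_id[i],
          to_id = states$state_id[match(state_label(to_status), states$state)],
          from = states$state[i],
          to = state_label(to_status),
          changed = paste(sub, collapse = "+"),
          moves = paste(products[sub], kinds, sep = ":", collapse = "+"),
          n_changed = length(sub)
        ),
        setNames(as.list(move_by_product), paste0("move_", products))
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out <- tibble::add_column(out, flow_id = seq_len(nrow(out)), .before = 1)
  if (anyDuplicated(out[, c("from", "to", "changed")]) > 0L) {
    abort("Internal error: duplicate (from, to, subset) flow triples.")
  }
  attr(out, "products") <- products
  out
}
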