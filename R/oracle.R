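#' Exhaustive maximum-link-satisfaction arrangement search
#'
#' Brute-force reference for validating the greedy extender on small
#' instances: enumerates every permutation and orientation assignment of
#' the given contigs (as a single linear arrangement) and scores each by
#' the number of clean links it satisfies. A link is satisfied when its two
#' contigs are adjacent in the arrangement with the link's end labels
#' facing each other. An arrangement and its global reversal always score
#' the same; the optimum is reported as unique when exactly one arrangement
#' class (up to reversal) attains the maximum.
#'
#' Per permutation the optimal orientation assignment is found by dynamic
#' programming along the chain, so instances up to 7-8 contigs are
#' practical.
#'
#' @param clean_links Clean link data.frame (with end labels).
#' @param contig_ids Contigs to arrange (at most ~8).
#' @return A list: `best_score`, `unique` (logical, up to reversal),
#'   `arrangement` (data.frame `contig_id`, `orientation` of one optimal
#'   arrangement), `n_optima` (number of optimal arrangements, reversals
#'   counted separately).
#' @export
exhaustive_scaffold_search <- function(clean_links, contig_ids) {
  n <- length(contig_ids)
  stopifnot(n >= 1)
  if (n > 8) stop("exhaustive search is limited to 8 contigs")
  support <- end_partner_support(clean_links)
  # S[i, ei, j, ej]: links between end ei of contig i and end ej of contig j
  S <- array(0, dim = c(n, 2, n, 2))
  ends <- c("5'" = 1L, "3'" = 2L)
  sub <- support[support$contig %in% contig_ids &
                   support$partner %in% contig_ids, , drop = FALSE]
  for (r in seq_len(nrow(sub))) {
    i <- match(sub$contig[r], contig_ids)
    j <- match(sub$partner[r], contig_ids)
    S[i, ends[sub$end[r]], j, ends[sub$partner_end[r]]] <-
      S[i, ends[sub$end[r]], j, ends[sub$partner_end[r]]] + sub$count[r]
  }
  S <- (S + aperm(S, c(3, 4, 1, 2))) / 2  # symmetrize double counting

  # right-facing end index for orientation o (1 = '+', 2 = '-')
  rf <- c(2L, 1L)  # '+' faces 3' right, '-' faces 5' right
  lf <- c(1L, 2L)  # '+' faces 5' left

  perms <- all_permutations(n)
  best_score <- -Inf
  best_count <- 0
  best_arrangement <- NULL
  for (p in perms) {
    # DP over orientations: f[o] = best score of prefix ending with orient o
    f <- c(0, 0)
    cnt <- c(1, 1)
    choice <- vector("list", n)  # backpointers
    for (i in seq_len(n)[-1]) {
      a <- p[i - 1]; b <- p[i]
      newf <- c(-Inf, -Inf); newc <- c(0, 0)
      bp <- matrix(0L, 2, 2)
      for (ob in 1:2) for (oa in 1:2) {
        v <- f[oa] + S[a, rf[oa], b, lf[ob]]
        if (v > newf[ob] + 1e-9) {
          newf[ob] <- v; newc[ob] <- cnt[oa]; bp[ob, 1] <- oa
        } else if (abs(v - newf[ob]) <= 1e-9) {
          newc[ob] <- newc[ob] + cnt[oa]
        }
      }
      f <- newf; cnt <- newc; choice[[i]] <- bp
    }
    mx <- max(f)
    n_opt <- sum(cnt[abs(f - mx) <= 1e-9])
    if (mx > best_score + 1e-9) {
      best_score <- mx
      best_count <- n_opt
      # traceback one optimal orientation assignment
      o <- integer(n)
      o[n] <- which.max(f)
      if (n > 1) for (i in n:2) o[i - 1] <- choice[[i]][o[i], 1]
      best_arrangement <- data.frame(
        contig_id = contig_ids[p],
        orientation = c("+", "-")[o],
        stringsAsFactors = FALSE)
    } else if (abs(mx - best_score) <= 1e-9) {
      best_count <- best_count + n_opt
    }
  }
  # a non-palindromic arrangement and its reversal are counted twice
  list(best_score = best_score,
       unique = best_count == 2 || (best_count == 1),
       arrangement = best_arrangement,
       n_optima = best_count)
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (s in sub) for (i in seq_len(n)) {
    k <- k + 1L
    out[[k]] <- append(s, n, after = i - 1L)
  }
  out
}

#' Compare two linear arrangements up to global reversal
#'
#' Two arrangements are equivalent when one equals the other or its
#' reversal with all orientations flipped.
#'
#' @param a,b Data.frames with columns `contig_id`, `orientation`.
#' @return TRUE or FALSE.
#' @export
same_arrangement <- function(a, b) {
  if (nrow(a) != nrow(b)) return(FALSE)
  fwd <- identical(a$contig_id, b$contig_id) &&
    identical(a$orientation, b$orientation)
  flip <- c("+" = "-", "-" = "+")
  rev_b <- data.frame(contig_id = rev(b$contig_id),
                      orientation = unname(flip[rev(b$orientation)]),
                      stringsAsFactors = FALSE)
  bwd <- identical(a$contig_id, rev_b$contig_id) &&
    identical(a$orientation, rev_b$orientation)
  fwd || bwd
}

#' Random well-linked scaffolding instance
#'
#' Generates a small instance with a known true arrangement for oracle and
#' extender validation: `n` big single-copy contigs in a random order and
#' orientation, clean links planted at every junction (count drawn around
#' `junction_links`), plus optional stray noise links below the support
#' threshold.
#'
#' @param n Number of contigs (2-8).
#' @param cfg An [sm_config()] object (contig sizes are set above
#'   `big_contig_min`).
#' @param junction_links Mean planted links per junction.
#' @param noise_links Number of stray single links between random
#'   non-adjacent contig ends.
#' @return A list: `contigs`, `clean_links`, `truth` (data.frame
#'   `contig_id`, `orientation` in true order).
#' @export
random_link_instance <- function(n, cfg, junction_links = 20,
                                 noise_links = 2) {
  ids <- sprintf("t%02d", seq_len(n))
  ord <- sample(ids)
  orient <- sample(c("+", "-"), n, replace = TRUE)
  lens <- as.integer(cfg$big_contig_min + sample(100:5000, n))
  contigs <- data.frame(contig_id = ids,
                        length = lens[match(ids, ord)],
                        coverage = 100, stringsAsFactors = FALSE)
  mk_link <- function(a, ea, b, eb, m) {
    if (m == 0) return(NULL)
    data.frame(read_id = sprintf("%s_%s_%d", a, b, seq_len(m)),
               contig_a = a, contig_b = b, end_a = ea, end_b = eb,
               orient_a = "+", orient_b = "+", pos_a = 1L, pos_b = 1L,
               insert = NA_integer_, intra = FALSE,
               stringsAsFactors = FALSE)
  }
  links <- list()
  for (i in seq_len(n - 1)) {
    m <- max(cfg$min_link_support,
             stats::rpois(1, junction_links))
    links[[i]] <- mk_link(ord[i], facing_end(orient[i], "right"),
                          ord[i + 1], facing_end(orient[i + 1], "left"), m)
  }
  for (k in seq_len(noise_links)) {
    pick <- sample(n, 2)
    if (abs(pick[1] - pick[2]) <= 1) next  # keep noise off true junctions
    links[[length(links) + 1]] <- mk_link(
      ord[pick[1]], sample(c("5'", "3'"), 1),
      ord[pick[2]], sample(c("5'", "3'"), 1), 1)
  }
  list(contigs = contigs,
       clean_links = do.call(rbind, links),
       truth = data.frame(contig_id = ord, orientation = orient,
                          stringsAsFactors = FALSE))
}
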