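# Mating pools, pair formation, offspring counts.

#' Assign individuals to mating pools
#'
#' Five pools exist: p0 (random maters) and p1..pK associated with the K
#' niches.  Individuals expressing random mating always join p0.  Assortative
#' maters join one of the niche pools, drawn with probabilities proportional
#' to their rounded (binary) response array: a `[1,0,0,0]` specialist joins p1
#' with probability 1, a `[1,0,1,0]` selective generalist joins p1 or p3 with
#' probability 0.5 each.  An assortative individual whose rounded array is all
#' zero has nowhere to congregate: it is left unassigned (`NA`) and skips
#' mating this generation.
#'
#' @param cls integer matrix of binary phenotype classes (individuals x
#'   niches), from [classifyPhenotype()].
#' @param behavior character vector of expressed mating behaviours, from
#'   [expressedMating()].
#' @return integer vector of pool labels: 0 for p0, 1..K for niche pools, NA
#'   for unassigned individuals.
#' @export
assignPools <- function(cls, behavior) {
  n <- nrow(cls)
  stopifnot(length(behavior) == n)
  pools <- integer(n)
  assort <- behavior == "assortative"
  if (any(assort)) {
    rs <- as.integer(rowSums(cls))
    pools[assort & rs == 0L] <- NA_integer_
    one <- assort & rs == 1L
    if (any(one))
      pools[one] <- max.col(cls[one, , drop = FALSE], ties.method = "first")
    for (i in which(assort & rs > 1L)) {
      bits <- which(cls[i, ] == 1L)
      pools[i] <- bits[sample.int(length(bits), 1L)]
    }
  }
  pools
}

#' Form mating pairs
#'
#' Pairs are formed sequentially: the first member of each pair is drawn
#' uniformly from all remaining unmated (pool-assigned) individuals; its
#' partner is drawn uniformly from its own pool if it sits in a niche pool
#' p1..pK, or from all remaining unmated individuals if it sits in p0.  Both
#' are then removed.  The asymmetry is deliberate: a random mater drawn first
#' can capture an assortative partner, but an assortative mater never reaches
#' outside its pool.  `strictP0 = TRUE` switches to the variant in which p0
#' members only ever pair within p0.  An individual drawn first with no
#' eligible partner is marked unmated and drawing continues until no one is
#' left.
#'
#' @param pools integer vector of pool labels from [assignPools()] (NA =
#'   skips mating).
#' @param strictP0 logical; see above (default FALSE).
#' @return integer matrix with two columns, one row per formed pair.
#' @export
formPairs <- function(pools, strictP0 = FALSE) {
  n <- length(pools)
  pairs <- matrix(0L, n %/% 2L, 2L)
  npairs <- 0L
  assigned <- which(!is.na(pools))
  if (length(assigned) < 2L) return(pairs[0, , drop = FALSE])

  # swap-remove bookkeeping: global availability plus per-pool member lists
  nPool <- max(pools, na.rm = TRUE)
  avail <- assigned
  aCount <- length(avail)
  aPos <- integer(n); aPos[avail] <- seq_len(aCount)
  members <- vector("list", nPool + 1L)
  pPos <- integer(n)
  pCount <- integer(nPool + 1L)
  for (p in 0:nPool) {
    m <- assigned[pools[assigned] == p]
    members[[p + 1L]] <- m
    pCount[p + 1L] <- length(m)
    pPos[m] <- seq_along(m)
  }

  while (aCount >= 2L) {
    first <- avail[sample.int(aCount, 1L)]
    # remove `first` from global availability and its pool (swap-remove)
    pos <- aPos[first]; last <- avail[aCount]
    avail[pos] <- last; aPos[last] <- pos
    aCount <- aCount - 1L
    pf <- pools[first] + 1L
    pos <- pPos[first]; last <- members[[pf]][pCount[pf]]
    members[[pf]][pos] <- last; pPos[last] <- pos
    pCount[pf] <- pCount[pf] - 1L

    if (pf >= 2L) {
      cn <- pCount[pf]
      if (cn == 0L) next  # unmated; keep drawing
      partner <- members[[pf]][sample.int(cn, 1L)]
    } else if (strictP0) {
      cn <- pCount[1L]
      if (cn == 0L) next
      partner <- members[[1L]][sample.int(cn, 1L)]
    } else {
      partner <- avail[sample.int(aCount, 1L)]
    }
    # remove the partner
    pos <- aPos[partner]; last <- avail[aCount]
    avail[pos] <- last; aPos[last] <- pos
    aCount <- aCount - 1L
    pp <- pools[partner] + 1L
    pos <- pPos[partner]; last <- members[[pp]][pCount[pp]]
    members[[pp]][pos] <- last; pPos[last] <- pos
    pCount[pp] <- pCount[pp] - 1L

    npairs <- npairs + 1L
    pairs[npairs, 1L] <- first
    pairs[npairs, 2L] <- partner
  }
  pairs[seq_len(npairs), , drop = FALSE]
}

#' Offspring count of a reproducing pair
#'
#' The number of recruits assigned to a pair is the nearest integer to the
#' mean fitness of its two members; exact half-values round up.
#'
#' @param f1,f2 non-negative fitness values (vectorised).
#' @return integer vector of offspring counts.
#' @examples
#' offspringCount(2.3, 2.6)  # round(2.45) = 2
#' @export
offspringCount <- function(f1, f2) {
  if (any(f1 < 0) || any(f2 < 0)) stop("fitness values must be non-negative")
  as.integer(floor((f1 + f2) / 2 + 0.5))
}
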