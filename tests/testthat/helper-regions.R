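# Fixture builders shared across the suite. Everything is generated in
# code; no binary fixtures.

# Wrap a patch (and optional mask) as a NucleusRegion without running the
# segmentation chain.
makeRegion <- function(px, mk = NULL, label = 1L) {
  px <- as.matrix(px)
  if (is.null(mk)) mk <- matrix(TRUE, nrow(px), ncol(px))
  new("NucleusRegion", label = as.integer(label),
      bbox = c(0L, 0L, nrow(px), ncol(px)),
      mask = mk, pixels = px * mk, area = sum(mk))
}

# Seeded random 16x16 patch with a blobby mask covering most of it.
randomPatch <- function(seed, n = 16L) {
  set.seed(seed)
  px <- matrix(sample(0:255, n * n, replace = TRUE), n, n)
  ctr <- (n + 1) / 2
  d <- sqrt((row(px) - ctr)^2 + (col(px) - ctr)^2)
  mk <- d <= (n / 2 - 1) + matrix(runif(n * n, -1, 1), n, n)
  # guarantee a usable mask
  if (sum(mk) < 10L) mk <- d <= n / 2 - 1
  list(px = px * mk, mk = mk, region = makeRegion(px, mk))
}

# A frame with dark filled disks on a bright background.
diskField <- function(frame = c(300L, 300L), centers, radius = 15,
                      fg = 80, bg = 200) {
  img <- matrix(bg, frame[1], frame[2])
  for (ctr in centers) {
    d <- sqrt((row(img) - ctr[1])^2 + (col(img) - ctr[2])^2)
    img[d <= radius] <- fg
  }
  img
}

# Digital disk mask.
diskMask <- function(n, radius, ctr = c((n + 1) / 2, (n + 1) / 2)) {
  m <- matrix(FALSE, n, n)
  d <- sqrt((row(m) - ctr[1])^2 + (col(m) - ctr[2])^2)
  d <= radius
}
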