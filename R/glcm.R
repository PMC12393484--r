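# Gray-level co-occurrence (Haralick) texture features.
#
# Symmetric GLCMs are accumulated for the four directions (0, 45, 90,
# 135 degrees) at a given pair distance, restricted to pixel pairs that
# both lie inside the mask; the 13 classic Haralick features are computed
# per direction and averaged. Direction averaging over symmetric GLCMs
# makes the features exactly invariant under 90-degree rotations.

glcm_feature_names <- c("asm", "con", "cor", "var", "idm", "sav", "sva",
                        "sen", "ent", "dva", "den", "f12", "f13")

# co-occurrence counts for one offset (dr, dc), symmetrized
glcm_counts <- function(q, dr, dc, nbins) {
  nr <- nrow(q); nc <- ncol(q)
  r1 <- max(1, 1 - dr):min(nr, nr - dr)
  c1 <- max(1, 1 - dc):min(nc, nc - dc)
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dr, c1 + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(matrix(0, nbins, nbins))
  idx <- (a[ok] - 1L) * nbins + b[ok]
  counts <- tabulate(idx, nbins = nbins * nbins)
  m <- matrix(counts, nbins, nbins, byrow = TRUE)
  m + t(m)
}

# the 13 Haralick features of one normalized symmetric GLCM
haralick_features_one <- function(p) {
  n <- nrow(p)
  i <- matrix(seq_len(n), n, n)
  j <- t(i)
  px <- rowSums(p)
  mu <- sum(seq_len(n) * px)
  sig2 <- sum((seq_len(n) - mu)^2 * px)

  asm <- sum(p^2)
  con <- sum((i - j)^2 * p)
  cor <- if (sig2 > 0) (sum(i * j * p) - mu^2) / sig2 else 0
  vvar <- sum((i - mu)^2 * p)
  idm <- sum(p / (1 + (i - j)^2))

  # p_{x+y}, k = 2..2n ; p_{x-y}, k = 0..n-1
  psum <- vapply(2:(2 * n), function(k) sum(p[i + j == k]), numeric(1))
  pdif <- vapply(0:(n - 1), function(k) sum(p[abs(i - j) == k]), numeric(1))
  ks <- 2:(2 * n); kd <- 0:(n - 1)
  sav <- sum(ks * psum)
  sva <- sum((ks - sav)^2 * psum)
  xlogx <- function(x) ifelse(x > 0, x * log(x), 0)
  sen <- -sum(xlogx(psum))
  ent <- -sum(xlogx(p))
  dva <- sum(kd^2 * pdif) - sum(kd * pdif)^2
  den <- -sum(xlogx(pdif))

  pxpy <- outer(px, px)
  hxy1 <- -sum(ifelse(pxpy > 0 & p > 0, p * log(pxpy), 0))
  hxy2 <- -sum(xlogx(pxpy))
  hx <- -sum(xlogx(px))
  f12 <- if (hx > 0) (ent - hxy1) / hx else 0
  f13 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - ent))))

  c(asm = asm, con = con, cor = cor, var = vvar, idm = idm, sav = sav,
    sva = sva, sen = sen, ent = ent, dva = dva, den = den, f12 = f12,
    f13 = f13)
}

# direction-averaged Haralick features at one pair distance
haralick_at_distance <- function(q, d, nbins) {
  offsets <- list(c(0, d), c(d, d), c(d, 0), c(d, -d))
  feats <- vapply(offsets, function(o) {
    counts <- glcm_counts(q, o[1], o[2], nbins)
    tot <- sum(counts)
    if (tot == 0) return(rep(0, 13))
    haralick_features_one(counts / tot)
  }, numeric(13))
  rowMeans(feats)
}

# quantize masked intensities to 1..nbins on the masked range; NA outside
quantize_masked <- function(img, mask, nbins) {
  q <- matrix(NA_integer_, nrow(img), ncol(img))
  vals <- img[mask]
  rng <- range(vals)
  if (diff(rng) > 0) {
    q[mask] <- pmin(nbins, 1L + as.integer(floor(
      (vals - rng[1]) / diff(rng) * nbins)))
  } else {
    q[mask] <- 1L
  }
  q
}
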