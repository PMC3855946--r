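# Shared fixtures. The abdominal phantom and its default-config simulation
# are expensive, so they are built once per test run and reused.

.fixtureCache <- new.env(parent = emptyenv())

cachedAbdominal <- function() {
  if (is.null(.fixtureCache$ph))
    .fixtureCache$ph <- makeAbdominalPhantom(seed = 1L)
  .fixtureCache$ph
}

cachedSim <- function() {
  if (is.null(.fixtureCache$sim)) {
    ph <- cachedAbdominal()
    cfg <- defaultConfig(seed = 42L)
    .fixtureCache$cfg <- cfg
    .fixtureCache$sim <- simulateUltrasound(cfg, volume = ph$volume,
                                            returnIntermediates = TRUE)
  }
  list(sim = .fixtureCache$sim, cfg = .fixtureCache$cfg,
       ph = cachedAbdominal())
}

cachedSimOff <- function() {
  if (is.null(.fixtureCache$simOff)) {
    ph <- cachedAbdominal()
    cfg <- defaultConfig(seed = 42L)
    cfg@enhance <- FALSE
    .fixtureCache$cfgOff <- cfg
    .fixtureCache$simOff <- simulateUltrasound(cfg, volume = ph$volume,
                                               returnIntermediates = TRUE)
  }
  list(sim = .fixtureCache$simOff, cfg = .fixtureCache$cfgOff,
       ph = cachedAbdominal())
}

# Resample a 3D ground-truth mask into the rectangular scanline domain of a
# given config/transform (same machinery the image itself went through).
rectDomainMask <- function(mask, volume, cfg, forwardTransform,
                           threshold = 0.5) {
  mv <- CTVolume(array(as.numeric(mask), dim(mask)), spacing(volume))
  sl <- extractSectorSlice(mv, cfg@apex, cfg@beamDir, cfg@lateralDir,
                           cfg@geometry, background = 0)
  rectGrid(resampleToRectangle(sl, cfg@geometry, forwardTransform,
                               background = 0)) > threshold
}

dilateMask <- function(m, iter = 1L) {
  for (k in seq_len(iter))
    m <- m | rbind(m[-1, ], FALSE) | rbind(FALSE, m[-nrow(m), ]) |
      cbind(m[, -1], FALSE) | cbind(FALSE, m[, -ncol(m)])
  m
}

erodeMask <- function(m, iter = 1L) {
  for (k in seq_len(iter))
    m <- m & rbind(m[-1, ], FALSE) & rbind(FALSE, m[-nrow(m), ]) &
      cbind(m[, -1], FALSE) & cbind(FALSE, m[, -ncol(m)])
  m
}

# Lumen/band intensity ratio on the 8-bit rectangular-domain image: the
# vessel-anechoicity measure (band = liver at the lumen's depth rows,
# excluding a 3-pixel rim around the lumen).
anechoicityRatio <- function(simList) {
  sim <- simList$sim; cfg <- simList$cfg; ph <- simList$ph
  fwd <- sim$transforms$forward
  vess <- rectDomainMask(ph$masks$vessels, ph$volume, cfg, fwd)
  liver <- rectDomainMask(ph$masks$liver, ph$volume, cfg, fwd)
  img <- linearScale256(sim$blurred)
  band <- liver & !dilateMask(vess, 3L)
  vrow <- which(rowSums(vess) > 0)
  band <- band & row(img) %in% vrow
  mean(img[vess]) / mean(img[band])
}
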