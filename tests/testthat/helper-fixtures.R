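# Shared fixture builders for the test suite. Everything is generated in
# code at test time; seeds are fixed so failures reproduce.

# strip an image_plane down to a plain matrix
as_matrix_for_test <- function(p) {
  m <- unclass(p)
  attributes(m) <- list(dim = dim(p))
  m
}

# match measured granules to the ground-truth table by nearest centroid;
# returns the truth row index for each measured row
match_truth <- function(measured, truth) {
  vapply(seq_len(nrow(measured)), function(i) {
    which.min((truth$row - measured$row[i])^2 + (truth$col - measured$col[i])^2)
  }, integer(1))
}

# segmentation -> measurement on a rendered scene, returning the granule
# table joined with its matched truth ratios
measure_scene <- function(scene, ...) {
  gl <- segment_granules(scene$marker, scene$cell_mask)
  gr <- measure_granules(gl, list(marker = scene$marker, probe = scene$probe), ...)
  if (nrow(gr) > 0L) {
    idx <- match_truth(gr, scene$truth)
    gr$true_ratio <- scene$truth$true_ratio[idx]
    gr$true_radius_px <- scene$truth$radius_px[idx]
  }
  gr
}

# a small uniform-plus-disk fixture with hand-controlled labels, bypassing
# segmentation, for exact-arithmetic enrichment checks
disk_fixture <- function(n = 64, center = c(32, 32), radius = 6,
                         inside = 300, outside = 100) {
  img <- matrix(outside, n, n)
  d <- (row(img) - center[1])^2 + (col(img) - center[2])^2 <= radius^2
  img[d] <- inside
  labels <- matrix(0L, n, n)
  labels[d] <- 1L
  regions <- structure(
    list(labels = labels, cell_mask = matrix(TRUE, n, n), n = 1L),
    class = "granule_labels"
  )
  list(img = image_plane(img, channel = "probe"), regions = regions, disk = d)
}

# rasterise a timelapse script straight to truth label frames and run the
# full tracking + event-calling chain
track_script <- function(script, shape = c(128L, 128L), max_link_px = 8) {
  tl <- render_timelapse(script, scene_spec(image_shape = shape),
                         what = "labels")
  det <- granule_detections(tl$frames)
  trk <- track_granules(det, max_link_px = max_link_px)
  list(timelapse = tl, detections = det, tracks = trk,
       events = call_events(trk))
}
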