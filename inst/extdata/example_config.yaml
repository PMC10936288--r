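# pennate pipeline configuration
# All angles are degrees (positive = structure rises toward the right of the
# screen), all lengths and distances are pixels, intensities are 0-255.

# Trial-wide ROI split: half-open [from, to) row/column intervals, 0-based.
# "top" holds the target fascicle, "bottom" the (near-horizontal) aponeurosis.
roi:
  top_rows: [0, 64]
  top_cols: [0, 256]
  bottom_rows: [64, 128]
  bottom_cols: [0, 256]

# Pixels dimmer than this are removed before clustering.
denoise_threshold: 100

# Optional elliptical brightness-augmentation filters, applied to the top
# sub-image only. Each filter contributes one candidate angle per frame; the
# no-augmentation path always runs in addition. Delete the list (or leave it
# empty) to run without augmentation.
augmentation_filters:
  - center: [128, 32]      # (col, row), 0-based, in top sub-image coordinates
    semi_major: 80
    semi_minor: 20
    rotation_deg: 10
    gain: 1.3

clustering:
  method: dbscan           # dbscan | kmeans | hac
  eps: 2.0                 # dbscan neighborhood radius
  min_pts: 5               # dbscan core-point count (self included)
  # k: 12                  # kmeans; omit to reuse the dbscan cluster count
  # seed: 0                # kmeans init; omit to use the frame index
  link_threshold: 2.0      # hac single-linkage distance (strict <)

merge:
  angle_tol_deg: 5         # max cluster-angle difference for a candidate pair
  connect_tol_deg: 5       # max |connection angle - mean cluster angle|
  max_gap_px: 40           # lateral gap cap between fragments
  plausibility: true
  fascicle_rises: right    # right | left: which end of the fascicle is shallower
  apo_max_angle_deg: 15    # bottom-ROI flatness bound

value:
  w: 0.6                   # weight on normalized length vs normalized brightness
  length_norm: 256
  brightness_norm: 65280   # 255 * 256

# Across-frame viscosity smoothing (skew-Gaussian weight on the increment
# between the measured and the predicted PA).
viscosity:
  location_deg: 0
  scale_deg: 2
  shape: 0
  amplitude: 1
  predictor: previous      # previous | linear_extrapolation

# Within-frame fusion of the per-filter angles.
fusion:
  epsilon: 1.0e-6
  lambda_floor: 1.0e-3
  viscosity:
    location_deg: 0
    scale_deg: 2
    shape: 0
    amplitude: 1

min_cluster_px: 15
smooth: true
frame_rate: 20
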