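# Geometric constraint tables for the head phantom generator.
#
# Every sampled quantity is given as {mean, hr}: the sampler draws values in
# [mean - hr, mean + hr] (truncated normal by default, sd = hr/2).
#
# Element size/centre semantics:
#   mode: offset   -> value is added to the reference ellipse: centres in the
#                     reference's tilted frame, sizes per semiaxis, tilts
#                     additively.
#   mode: absolute -> value is an absolute semiaxis length (mm) or an angle
#                     in head coordinates.
#
# circumference entries are in mm; circumference_ratio entries are relative
# to the Inner ellipse circumference (for lup/rup the constraint applies to
# the *sum* of the upper and lower lobe circumferences, see `sum_with`).
# axes_ratio is semi_y / semi_x. Constraints with `enforce: false` are
# reported by the geometry validator but not used for rejection: they are
# mutually infeasible with the size ranges (see the package vignette).

image:
  extent_mm: 234.0     # field of view of the property/target images
  target_px: 64        # reconstruction image resolution
  area_check_px: 128   # raster used for area-fraction rejection tests

head:
  semi_x: 77.0         # fixed outline: 575 mm circumference belt
  semi_y: 105.0
  center: [0.0, 0.0]
  tilt: 0.0
  skin_thickness_mm: 3.0
  # Outline statistics of the manually fitted models; the simulated outline
  # is fixed, so these are carried for reference and never sampled.
  measured:
    center_x: {mean: 2.0, hr: 3.0}
    center_y: {mean: 14.0, hr: 8.0}
    size_x:   {mean: 91.0, hr: 20.0}
    size_y:   {mean: 99.0, hr: 12.0}
    tilt:     {mean: -2.5, hr: 8.5}
    circumference: {mean: 570.0, hr: 70.0}
    axes_ratio:    {mean: 1.2, hr: 0.2}

# Dividing line between the hemispheres: vertical line shifted and tilted.
midline:
  shift_x: {mean: -3.0, hr: 6.0}
  shift_y: {mean: -8.5, hr: 10.5}
  tilt:    {mean: 1.0, hr: 10.0}

elements:
  inner:
    reference: head
    center_x: {mean: -0.5, hr: 2.5, mode: offset}
    center_y: {mean: -1.5, hr: 4.5, mode: offset}
    size_x:   {mean: -14.0, hr: 5.0, mode: offset}
    size_y:   {mean: -14.0, hr: 5.0, mode: offset}
    tilt:     {mean: 2.0, hr: 10.0, mode: offset}
    circumference: {mean: 487.5, hr: 53.5, enforce: true}
    axes_ratio:    {mean: 1.3, hr: 0.2, enforce: true}
  ldown:
    reference: inner
    hemisphere: left
    center_x: {mean: -25.5, hr: 9.5, mode: offset}
    center_y: {mean: -21.5, hr: 9.5, mode: offset}
    size_x:   {mean: -23.5, hr: 14.5, mode: offset}  # printed range typo: hr taken as |−14.5|
    size_y:   {mean: -50.0, hr: 12.0, mode: offset}
    tilt:     {mean: -72.5, hr: 12.5, mode: offset}
    circumference_ratio: {mean: 0.7, hr: 0.1, enforce: false}
    axes_ratio:          {mean: 0.6, hr: 0.1, enforce: false}
  lup:
    reference: inner
    hemisphere: left
    center_x: {mean: -24.5, hr: 7.5, mode: offset}
    center_y: {mean: 24.0, hr: 10.0, mode: offset}
    size_x:   {mean: -30.5, hr: 7.5, mode: offset}
    size_y:   {mean: -32.0, hr: 9.0, mode: offset}
    tilt:     {mean: -20.0, hr: 22.0, mode: offset}
    circumference_ratio: {mean: 1.3, hr: 0.1, enforce: false, sum_with: ldown}
    axes_ratio:          {mean: 1.8, hr: 0.5, enforce: false}
  rdown:
    reference: inner
    hemisphere: right
    center_x: {mean: 25.5, hr: 6.5, mode: offset}
    center_y: {mean: -20.0, hr: 11.0, mode: offset}
    size_x:   {mean: -25.5, hr: 17.5, mode: offset}  # printed range typo: hr taken as |−17.5|
    size_y:   {mean: -54.5, hr: 11.5, mode: offset}
    tilt:     {mean: 72.5, hr: 11.5, mode: offset}
    circumference_ratio: {mean: 0.6, hr: 0.1, enforce: false}
    axes_ratio:          {mean: 0.5, hr: 0.1, enforce: false}
  rup:
    reference: inner
    hemisphere: right
    center_x: {mean: 27.0, hr: 7.0, mode: offset}
    center_y: {mean: 26.0, hr: 13.0, mode: offset}
    size_x:   {mean: -32.0, hr: 9.0, mode: offset}
    size_y:   {mean: -33.5, hr: 7.5, mode: offset}
    tilt:     {mean: 29.0, hr: 15.0, mode: offset}
    circumference_ratio: {mean: 1.3, hr: 0.1, enforce: false, sum_with: rdown}
    axes_ratio:          {mean: 1.6, hr: 0.5, enforce: false}
  center_csf:
    reference: inner
    center_x: {mean: 0.5, hr: 2.5, mode: offset}
    center_y: {mean: -2.5, hr: 13.5, mode: offset}
    size_x:   {mean: -54.5, hr: 8.5, mode: offset}
    size_y:   {mean: -53.0, hr: 15.0, mode: offset}
    tilt:     {mean: 2.0, hr: 9.0, mode: offset}
    circumference_ratio: {mean: 0.3, hr: 0.1, enforce: true}
    axes_ratio:          {mean: 4.4, hr: 2.9, enforce: true}

# Satellite CSF ellipses: positioned at an angular position on the central
# CSF ellipse, shifted along the outward-pointing normal at that point.
satellites:
  csf1:
    axis_angle: {mean: 149.5, hr: 10.5}
    shift:      {mean: 8.5, hr: 1.5}
    size_x:     {mean: 17.5, hr: 2.5, mode: absolute}
    size_y:     {mean: 9.0, hr: 1.0, mode: absolute}
    tilt:       {mean: -27.0, hr: 6.0, mode: absolute}
    circumference: {mean: 93.5, hr: 24.5, enforce: true}
    axes_ratio:    {mean: 0.3, hr: 0.2, enforce: true}
  csf2:
    axis_angle: {mean: 25.0, hr: 23.0}
    shift:      {mean: 8.5, hr: 1.5}
    size_x:     {mean: 18.0, hr: 2.0, mode: absolute}
    size_y:     {mean: 9.0, hr: 1.0, mode: absolute}
    tilt:       {mean: 22.0, hr: 5.0, mode: absolute}
    circumference: {mean: 94.0, hr: 22.0, enforce: true}
    axes_ratio:    {mean: 0.4, hr: 0.2, enforce: true}
  csf3:
    axis_angle: {mean: -51.0, hr: 11.0}
    shift:      {mean: 1.5, hr: 4.5}
    size_x:     {mean: 13.0, hr: 5.0, mode: absolute}
    size_y:     {mean: 5.5, hr: 2.5, mode: absolute}
    tilt:       {mean: 5.5, hr: 5.5, mode: absolute}
    circumference: {mean: 57.0, hr: 21.0, enforce: true}
    axes_ratio:    {mean: 0.5, hr: 0.3, enforce: true}
  csf4:
    axis_angle: {mean: -130.5, hr: 13.5}
    shift:      {mean: 1.5, hr: 4.5}
    size_x:     {mean: 16.0, hr: 5.0, mode: absolute}
    size_y:     {mean: 5.0, hr: 2.0, mode: absolute}
    tilt:       {mean: -6.0, hr: 6.0, mode: absolute}
    circumference: {mean: 70.0, hr: 23.0, enforce: true}
    axes_ratio:    {mean: 0.3, hr: 0.3, enforce: true}

# Global area constraints on every accepted sample. brain_fraction and
# rest_fraction are percentages of total image area; csf_fraction is a
# percentage of the head area (the only base consistent with the geometry,
# see the vignette); hemisphere_ratio is left/right brain area in percent.
area_constraints:
  brain_fraction:   {mean: 23.0, hr: 6.0}
  csf_fraction:     {mean: 23.0, hr: 6.0}
  rest_fraction:    {mean: 13.5, hr: 5.5}
  hemisphere_ratio: {mean: 98.5, hr: 7.5}

sampling:
  law: truncnorm         # or: uniform
  max_attempts: 10000    # global rejection budget
  local_attempts: 1000   # per-element rejection budget
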