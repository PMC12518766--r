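# spineforge

Automated preprocessing of patient-specific lumbar-spine finite-element
models in R.

Building a lumbar FE model by hand — separating cortical from cancellous
bone, carving each intervertebral disc into nucleus pulposus and annulus
fibrosus, finding the endplates, attaching ligaments, filling the
vertebra–disc gaps with cartilage, and wiring up materials, contacts and
loads — takes days of interactive CAD work per subject and is the main
bottleneck of subject-specific spinal biomechanics. spineforge automates
the entire chain: it consumes labeled surface meshes (`L1.stl` … `L5.stl`,
`D1.stl` … `D4.stl`, millimetres, as exported by any CT segmentation
pipeline) and emits a complete model in FEBio-format XML and legacy VTK.
It is aimed at biomechanics groups who already have segmentations and want
reproducible, scriptable model generation.

## The geometry pipeline

For a mesh $\mathcal{M} = (V, F)$ of each vertebra, the cancellous core is
the inward offset along area-weighted vertex normals,

$$V_{\text{cancellous}} = V_{\text{cortical}} - t_{\text{core}}\; n(v),
\qquad t_{\text{core}} = 0.3\ \text{mm},$$

regularized by synchronous Laplacian smoothing
$v \leftarrow (1-\lambda)\,v + \lambda\, \overline{N(v)}$ with
$0 < \lambda \le 1$; the cortical shell is the prism layer between the two
surfaces and the core volume a star-kernel fan mesh, so shell + core equals
the whole-vertebra volume by construction.

Each disc is oriented by PCA (covariance
$\Sigma = \tfrac{1}{n-1}\sum_i v_i' v_i'^{\mathsf T}$; $u_3$ = least
variance = disc axis). The projected outline is shrunk about its centroid,
$C_{\text{nucleus}} = s\, C_{\text{disc}}$ (default $s = 0.6$), swept along
$u_3$ and clipped to the disc; disc faces with any vertex inside that
volume are nucleus faces, the rest annulus. The two cap regions are joined
by a watertight wall whose nodes are shared bitwise between the nucleus and
annulus solids.

Endplates follow a four-step geometric recipe (upward faces → upper half
along the least-variance axis → largest 1.5 mm single-linkage cluster →
radial shrink to the 70th percentile; the lower endplate uses a parallel
plane 20 mm below and a 55%-of-max-radius shrink). Ligaments (ALL, ITL,
CL, SSL/ISL, PLL, LF) attach on half-spaces cut by planes through the
vertebral center with spherically parameterized normals
$N = r(\sin\phi\cos\theta, \sin\phi\sin\theta, \cos\phi)$ from a published
parameter table, 10 linear springs per ligament. Cartilage fills each
vertebra–disc gap by sweeping the endplate patch onto the disc contact
region. Assembly adds the constitutive set (cortical 12 000 MPa / 0.3,
cancellous 100 MPa / 0.2, Mooney–Rivlin nucleus and annulus, cartilage
23.8 MPa / 0.4, ligament springs E = 0.22 MPa), stick / tied /
node-to-surface contacts with a 0.01 mm node tolerance, a fully
constrained L5 lower endplate, rigid L1-upper / L5-lower endplates, and
four physiological load cases (extension, flexion, axial rotation, lateral
bending).

A deterministic synthetic L1–L5 generator (`make_lumbar_stack()`) provides
closed vertebra-like and disc-like meshes with the structure the pipeline
keys on, so everything is testable without patient data.

## Worked example

```r
library(spineforge)

params <- spine_params(seed = 1)       # synthetic stack; use read_spine_dir() for STL input
vertebra <- make_vertebra(params, 1)
vertebra
#> trimesh: 2562 vertices, 5120 faces, closed

split_vertebra(vertebra)
#> bone_split: outer 19430.5 mm^3 = shell 3000.3 + core 16434.2 (closure 100.02%)

disc <- make_disc(params, 1)
split_disc(disc)
#> disc_partition: 2830 nucleus + 2290 annulus faces; nucleus 3191.2 mm^3, annulus 3521.4 mm^3

ep <- extract_endplates(vertebra)
ep$upper
#> endplate_patch (upper): 782 vertices, 1474 faces, centroid (-0.1, 2.4, 149.0)
```

The bone split line says the vertebra's 19 430 mm³ were partitioned into a
3 000 mm³ cortical shell and a 16 434 mm³ cancellous core that close the
balance to 0.02%. The disc line reports the face partition and the two
solid volumes (nucleus ≈ 47% of the disc here because the any-vertex-inside
rule dilates the footprint by one face ring). The endplate centroid sits on
the top of the vertebral body (z = 149 mm is the L1 cap height in the
synthetic stack).

The full model:

```r
pl <- build_spine_model(make_lumbar_stack(params))
pl$model
#> fe_model: 26 parts, 320 springs, contacts [node_to_surface=32, stick=4, tied=8], 4 load cases

export_feb(pl$model, "model.feb")
export_vtk(pl$model, "vtk_out")
```

26 parts = 5 cortical + 5 cancellous + 4 nucleus + 4 annulus + 8 cartilage
segments (labeled `L1D1` … `L5D4`); 320 springs = 10 per ligament × 8
ligament instances × 4 motion segments.

A command-line front end wrapping these calls lives at
`inst/cli/spineforge.R` (`synth`, `split-bone`, `split-disc`, `endplates`,
`run-all`).

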