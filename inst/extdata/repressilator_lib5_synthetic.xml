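<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic five-component repression library (LacI/TetR/CI ring parts,
     a GFP-targeting repressor and an unrelated AraC part).  Constructed
     for the worked repressilator compilation; not measured data. -->
<library version="1">
  <component name="Q1"><gubs>LacI o-&gt; !TetR_lite</gubs></component>
  <component name="Q2"><gubs>CI o-&gt; !LacI</gubs></component>
  <component name="Q3"><gubs>TetR_lite o-&gt; !CI</gubs></component>
  <component name="Q4"><gubs>TetR_lite o-&gt; !GFP</gubs></component>
  <component name="Q5"><gubs>AraC o-&gt; !GFP</gubs></component>
</library>
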