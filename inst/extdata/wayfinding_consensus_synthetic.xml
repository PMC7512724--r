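<?xml version="1.0" encoding="UTF-8"?>
<BIF VERSION="0.3">
<NETWORK>
<NAME>wayfinding</NAME>
<VARIABLE TYPE="nature">
  <NAME>Human Factors</NAME>
  <OUTCOME>Good</OUTCOME>
  <OUTCOME>Bad</OUTCOME>
</VARIABLE>
<VARIABLE TYPE="nature">
  <NAME>Navigation Pathway</NAME>
  <OUTCOME>Simple</OUTCOME>
  <OUTCOME>Complex</OUTCOME>
</VARIABLE>
<VARIABLE TYPE="nature">
  <NAME>Visual Elements of Communication</NAME>
  <OUTCOME>Good</OUTCOME>
  <OUTCOME>Bad</OUTCOME>
</VARIABLE>
<VARIABLE TYPE="nature">
  <NAME>Environmental Factors</NAME>
  <OUTCOME>Good</OUTCOME>
  <OUTCOME>Bad</OUTCOME>
</VARIABLE>
<VARIABLE TYPE="nature">
  <NAME>Communication</NAME>
  <OUTCOME>Effective</OUTCOME>
  <OUTCOME>Ineffective</OUTCOME>
</VARIABLE>
<VARIABLE TYPE="nature">
  <NAME>Wayfinding</NAME>
  <OUTCOME>Effective</OUTCOME>
  <OUTCOME>Ineffective</OUTCOME>
</VARIABLE>
<DEFINITION>
  <FOR>Human Factors</FOR>
  <TABLE>0.75 0.25</TABLE>
</DEFINITION>
<DEFINITION>
  <FOR>Navigation Pathway</FOR>
  <TABLE>0.65000000000000002 0.34999999999999998</TABLE>
</DEFINITION>
<DEFINITION>
  <FOR>Visual Elements of Communication</FOR>
  <TABLE>0.80000000000000004 0.20000000000000001</TABLE>
</DEFINITION>
<DEFINITION>
  <FOR>Environmental Factors</FOR>
  <GIVEN>Navigation Pathway</GIVEN>
  <TABLE>0.84999999999999998 0.14999999999999999 0.55000000000000004 0.45000000000000001</TABLE>
</DEFINITION>
<DEFINITION>
  <FOR>Communication</FOR>
  <GIVEN>Visual Elements of Communication</GIVEN>
  <TABLE>0.84999999999999998 0.14999999999999999 0.40000000000000002 0.59999999999999998</TABLE>
</DEFINITION>
<DEFINITION>
  <FOR>Wayfinding</FOR>
  <GIVEN>Human Factors</GIVEN>
  <GIVEN>Environmental Factors</GIVEN>
  <GIVEN>Communication</GIVEN>
  <TABLE>0.94999999999999996 0.050000000000000003 0.80000000000000004 0.20000000000000001 0.80000000000000004 0.20000000000000001 0.59999999999999998 0.40000000000000002 0.59999999999999998 0.40000000000000002 0.40000000000000002 0.59999999999999998 0.34999999999999998 0.65000000000000002 0.10000000000000001 0.90000000000000002</TABLE>
</DEFINITION>
</NETWORK>
</BIF>
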