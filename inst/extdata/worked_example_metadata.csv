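CaptureEventID,NumImages,DateTime,SiteID,LocationX,LocationY
ASG0010cz5,3,2011-02-17 10:21:16,B04,664543,9696619
ASG0000009,1,2011-03-02 22:10:05,D09,671251,9701412
ASG000xzxd,3,2012-10-05 08:14:59,F06,675723,9705190
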